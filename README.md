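# distfrac

Detection **and** quantification of introgression on a four-taxon tree
(((P1,P2),P3),O) from SNP data, through the **distance fraction** `d_f`
and its companions — Patterson's `D`, `f_hom` and `f_d` — all expressed in
terms of average pairwise nucleotide diversity (`d_xy`).

Hybridization leaves a footprint in genetic distance: gene flow from P3
into P2 pulls `d_23` down while leaving `d_13` untouched.  Writing the
classic ABBA/BABA site patterns as frequency-weighted distances gives

```
D    =  Σ (p2·d13 − p1·d23)  /  Σ (p3·d12)
f_d  =  Σ (p2·d13 − p1·d23)  /  Σ (pD·d1D − p1·πD),   pD = max(p2, p3)
d_f  =  Σ (p2·d13 − p1·d23)  /  Σ (p2·d13 + p1·d23)
```

with `d_xy = p_x(1−p_y) + (1−p_x)p_y` per biallelic site.  `D`'s
denominator collapses in low-diversity windows, which is why `D` misbehaves
in sliding-window scans.  `d_f` instead adds the species-tree (BBAA) shared
distance to the denominator: it stays in `[−1, 1]`, is antisymmetric in
P1/P2 (positive for P3⇔P2 gene flow, negative for P3⇔P1), and estimates
the *fraction* of introgression `f` rather than merely flagging it.

The package is aimed at population genomicists running window-based
introgression scans (VCFs of phased haplotypes, simulated ms/seq-gen-style
data, or alignments) and at methodologists who want the accompanying
coalescent simulation and estimator-accuracy machinery.

## What's inside

- `read_vcf()`, `read_alignment()`, `read_ms()` / `write_ms()`,
  `read_popmap()` — haplotype input with logged site filters;
  `polarize()` orients alleles by the outgroup (strict or major-allele
  policy) and `site_frequencies()` builds the per-site frequency table.
- `patterson_d()`, `f_hom()`, `f_d()`, `d_f()`, `window_stats()` — the
  statistics, with optional Laplace smoothing `(count+1)/(n+2)` of p1/p2
  for small windows.
- `sim_config()`, `simulate_locus()`, `simulate_grid()`,
  `simulate_chromosome()` — a compiled structured-coalescent simulator
  (recombination, one admixture pulse, HKY or infinite-sites mutations)
  for the four-population history.
- `window_scan()`, `jackknife_z()`, `bh_fdr()`, `call_outliers()`,
  `write_scan()` — consecutive-window scans with weighted block-jackknife
  Z-values, BH-FDR q-values and TSV/BED output.
- `run_accuracy_experiment()`, `run_detection_experiment()`,
  `dxy_vs_f_curves()`, `fit_metrics()` — the evaluation harness (adjusted
  R², SSLF, SSPE, ROC AUC).
- `exec/distfrac` — a command-line front end with `stats`, `scan`,
  `simulate` and `evaluate` subcommands (`distfrac_cli()` from R).

## Worked example

Simulate one 5 kb locus under the baseline history (splits at 1/2/3 ×4N
generations, a pulse of `f = 0.5` from P3 into P2 at 0.1 ×4N, rho = 50,
HKY with branch scale 0.01), polarize by the outgroup, and compute the
statistics:

```r
library(distfrac)
set.seed(7)
cfg <- sim_config(f = 0.5, direction = "P3->P2")
hm  <- polarize(simulate_locus(cfg), "strict")
window_stats(site_frequencies(hm))[, c("n_snps", "D", "f_hom", "f_d", "d_f")]
#>   n_snps         D     f_hom       f_d       d_f
#> 1    616 0.9229297 0.5440575 0.5271858 0.6445094
```

`D` has saturated near 1 — it detects the event but badly overstates it —
while `d_f` and `f_d` sit near the simulated fraction 0.5 (any single 5 kb
locus is noisy; averaged over 100 replicate loci per fraction, the OLS fit
of `d_f` on the true `f` has adjusted R² ≈ 0.81 and per-fraction bias near
zero, against R² ≈ 0.40 and a strong positive bias for `D`:
`run_accuracy_experiment(sim_config(), reps = 100, seed = 101)`).

A genome scan on a synthetic 500 kb chromosome with a planted introgressed
tract at 200–300 kb:

```r
set.seed(61)
chrom <- simulate_chromosome(sim_config(f = 0, model = "infinite_sites"),
                             n_loci = 100, tract = c(200000, 300000),
                             tract_f = 0.8)
sc <- jackknife_z(window_scan(chrom, 25000, 25000))  # Laplace-smoothed
head(sc[order(-abs(sc$Z)), c("window_start", "window_end", "n_snps", "d_f", "Z", "q")], 5)
#>    window_start window_end n_snps     d_f      Z     q
#> 12       275000     300000   4120 0.50888 2.7055 0.095
#> 11       250000     275000   3977 0.49651 2.5935 0.095
#> 10       225000     250000   4308 0.42195 2.2939 0.126
#> 9        200000     225000   4156 0.41915 2.2381 0.126
#> 6        125000     150000   4594 0.00772 0.0433 1.000
```

The four tract windows carry the top smoothed `d_f` and `Z` values, well
separated from the background; on a short 20-window fixture like this the
BH q-values stay above 0.05 (the tract itself inflates the between-block
jackknife variance), while on chromosome-arm-scale scans
`call_outliers(sc)` reports the windows per significance tier.

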