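---
title: "Measuring introgression with the distance fraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring introgression with the distance fraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(distfrac)
```

## The model

`distfrac` works on the four-taxon species tree (((P1,P2),P3),O): two
sister populations P1 and P2, a candidate donor P3, and an outgroup O that
defines the ancestral allele.  At a biallelic site $k$ with derived-allele
frequencies $p_{1k},\dots,p_{4k}$, the average pairwise distance between
populations $x$ and $y$ is

$$d_{xyk} = p_{xk}(1-p_{yk}) + (1-p_{xk})p_{yk},$$

the mean mismatch over all haplotype pairs.  The classic ABBA and BABA
introgression patterns are, in this currency, polarized shared distances:
ABBA is distance shared by (P2,P3) against P1, BABA is distance shared by
(P1,P3) against P2, and the species-tree pattern BBAA is distance shared by
(P1,P2) against P3.  Summed over a window of $L$ variant sites this gives
the distance form of Patterson's $D$,

$$D = \frac{\sum_k p_{2k} d_{13k} - p_{1k} d_{23k}}{\sum_k p_{3k} d_{12k}},$$

whose denominator — $p_3$ times the *diversity between P1 and P2* — is the
root of $D$'s notorious behaviour in small or low-diversity windows: when
$d_{12}$ collapses, $D$ explodes towards $\pm 1$.  The admixture-fraction
estimators keep the same numerator and swap the denominator: `f_hom` uses
$\sum p_{3k} d_{13k} - p_{1k}\pi_{3k}$ (complete P3→P2 introgression
homogenizes P2 and P3, driving the statistic to 1) and `f_d` substitutes,
per site, the population $P_D \in \{P2, P3\}$ with the higher derived
frequency.  The package's central statistic, the distance fraction

$$d_f = \frac{\sum_k p_{2k} d_{13k} - p_{1k} d_{23k}}
             {\sum_k p_{2k} d_{13k} + p_{1k} d_{23k}},$$

adds the BBAA shared distance into the denominator so that *all* ways two
populations can share derived distance on the tree are represented.  It is
bounded in $[-1, 1]$ whenever defined, antisymmetric under a P1/P2 swap
(positive for P3⇔P2 gene flow, negative for P3⇔P1), and estimates the
introgression *fraction* $f$ rather than merely detecting its presence.

```{r}
fr <- data.frame(position = 0:2,
                 p1 = c(0, 1, 1), p2 = c(1, 0, 1), p3 = c(1, 1, 0),
                 p4 = 0, n1 = 8, n2 = 8, n3 = 8, n4 = 8,
                 c1 = c(0, 8, 8), c2 = c(8, 0, 8), c3 = c(8, 8, 0),
                 c4 = 0)
c(abba_site = d_f(fr[1, ]), baba_site = d_f(fr[2, ]), bbaa_site = d_f(fr[3, ]))
```

A fixed BBAA site leaves the numerator untouched but grows the
denominator — exactly the damping that keeps windows dominated by
species-tree signal near zero.

## Estimator conventions

* **Within-population diversity** uses the frequency form
  $\pi = 2p(1-p)$ with no $n/(n-1)$ correction, matching the frequency
  form of $d_{xy}$; `site_pi(..., unbiased = TRUE)` exposes the corrected
  variant for users who want consistency with other software.
* **$P_D$ ties** ($p_2 = p_3$) resolve to P3.  The choice is provably
  value-irrelevant — $p_D$, $d_{1D}$ and $\pi_D$ coincide — and exists only
  to make the code path deterministic.
* **Outgroup handling.**  The printed statistics carry no $p_4$ term, so the
  default `polarize(x, "strict")` keeps only sites where the outgroup is
  fixed and recodes them so $p_4 = 0$; the count of discarded sites is
  logged.  `polarize(x, "major")` instead calls the outgroup's major allele
  ancestral and keeps everything except exact 50/50 ties, for which no
  defensible ancestral call exists.
* **Zero denominators** yield `NaN`, never an error: a scan across a
  chromosome must survive BBAA-only or empty windows.  Undefined windows
  are flagged by `n_snps` and excluded from downstream metrics with
  logged counts.
* **Laplace smoothing** replaces $p_1$ and $p_2$ (only) by
  $(\text{count}+1)/(n+2)$ and rebuilds every distance term from the
  smoothed values.  It is off for whole-window estimates and on by default
  in `window_scan()`, where small windows with $p_1 = p_2 = 0$ would
  otherwise produce extreme values.
* **Coordinates** are 0-based and half-open everywhere.
* Sites monomorphic across all four populations are skipped; multiallelic
  sites and sites with an uncalled population are dropped with counters.

## The simulator

`sim_config()` + `simulate_locus()` generate data under a structured
coalescent with recombination for the four-population history, written the
way the field's simulators are (a compiled Hudson-style ancestral
recombination graph), with times in units of $4N$ generations:

* split times `t12 = 1`, `t123 = 2`, `t123O = 3` (the "1-2-3" history;
  `t12 = t123 = 1` gives the "1-1-3" trident),
* one admixture pulse of fraction `f` at `t_gf = 0.1`, direction
  `P3->P2` by default (implemented backwards in time as each recipient
  lineage jumping into the donor with probability `f`; `P2->P3` and
  `P3->P1` are the mirrored pulses),
* recombination `rho = 50` across a 5 kb locus, 8 haplotypes per
  population,
* HKY substitutions with branch scale `s = 0.01` substitutions per site
  per $4N$ generations, i.e. about 1% within-population diversity.

The HKY model's transition/transversion ratio and base frequencies are
nuisance parameters that the classic pipeline leaves at tool defaults; we
fix `kappa = 2` and equal base frequencies, configurable in
`sim_config()`.  The statistics are frequency ratios and are insensitive
to these within reason.  An `infinite_sites` model is provided at matched
expected density; it skips sequence space entirely, knows the true
ancestral allele, and is noticeably faster, which the test-suite exploits.
The HKY path instead produces genuine nucleotide columns that must be
polarized by the outgroup — including the sites the outgroup gets wrong —
and is the default because real analyses face exactly that noise.

What the generator does **not** emulate: continuous migration (only a
single pulse), selection, mutation-rate or recombination-rate
heterogeneity along the genome, sequencing error and missing data.
Passing simulation-based checks therefore says the estimators behave under
the idealized demographic model, not that every real-data complication is
harmless.

Simulator correctness is pinned by closed-form checks (a specific pair's
expected coalescence time is invariant to sampling more lineages; expected
segregating sites $E[S] = sLH_{n-1}$ in the near-panmictic limit; $E[D] =
0$ at $f = 0$) rather than by comparison against any particular external
tool.

## The genome scan

`window_scan()` tiles a region with consecutive (or stepping) windows —
50 kb consecutive windows being the chromosome-arm convention — and
computes all four statistics per window with Laplace smoothing on.
`jackknife_z()` attaches significance.  The exact weighted-jackknife
recipe behind per-window Z-values in the literature is not something one can read
off a methods section, so the package states its own convention precisely:

1. Blocks default to the scan windows themselves (configurable via
   `blocks`).
2. The pooled ratio statistic over all blocks is jackknifed with the
   Busing-style weighted delete-one formula, block weights proportional to
   SNP counts (`weights = "equal"` recovers the textbook delete-one
   jackknife exactly; this is regression-tested against a naive loop).
3. The pooled variance is mapped back to block scale by
   $SE_j = \sqrt{h_j}\, SE_{pooled}$ with $h_j = n/m_j$, so each window's
   Z-value, $(\hat\theta_j - \theta_0)/SE_j$, is measured against the
   chromosome-wide sampling variability of a window-sized chunk of data,
   with SNP-rich windows held to a tighter standard error.
4. Two nulls: $\theta_0 = 0$ everywhere (`null = "zero"`), or, for windows
   inside a declared region, the region's pooled statistic
   (`null = "mean"`) — the test used inside an inversion already known to
   be an outlier, where the question is deviation from the local mean.

Two-sided p-values come from the normal distribution (introgression sign
is meaningful in both directions) and are Benjamini–Hochberg adjusted;
`call_outliers()` reports the 0.05 and 0.01 tiers, nested by
construction.

## The evaluation harness

`run_accuracy_experiment()` reproduces the accuracy protocol: for each
$f$ in a grid (default $0, 0.1, \dots, 1$) simulate `reps` loci (default
100), compute each statistic per locus, and score with

* adjusted $R^2$ of the OLS fit of estimate on $f$ (the "goodness of
  fit").  The alternative reading — $R^2$ about the identity line
  $y = f$ — is available as `fit_metrics(..., r2 = "identity")` because the
  regression specification behind such accuracy tables varies across reports; the
  regression form is the default since a "goodness of fit" of statistic
  against true fraction is most naturally the OLS fit.
* SSLF, the lack-of-fit sum $\sum_j n_j(\bar y_j - f_j)^2$, reported
  divided by the per-fraction sample size;
* SSPE, the pure-error sum $\sum_{ij} (y_{ij} - \bar y_j)^2$.  The
  `eval_report` carries SSPE raw; comparisons against literature
  per-100-locus tables should divide by the per-fraction count, which is
  how the acceptance script reports it.

`run_detection_experiment()` scores each statistic's ability to separate
introgressed from neutral loci by ROC AUC (via pROC), and
`dxy_vs_f_curves()` traces how the three pairwise distances respond to
$f$: a P3→P2 pulse erodes $d_{23}$ linearly while leaving $d_{13}$ flat,
and mirrored for P2→P3 with $d_{12}$ — the asymmetry that carries
directional information.

```{r}
cfg <- sim_config(f = 0.5, L = 2000, model = "infinite_sites")
rep_small <- run_accuracy_experiment(cfg, f_values = c(0, 0.5, 1),
                                     reps = 10, seed = 1)
rep_small$metrics
```

Monte-Carlo assertions in the test-suite run seeded and use tolerance
bands of a few Monte-Carlo standard errors.  Problem sizes are chosen so
the full suite stays desk-scale: the accuracy-grid checks run the
canonical 100 loci × 11 fractions; the gene-flow-timing and direction
checks run 40–50 loci per fraction; the detection check runs hundreds
rather than 11,000 loci, since AUC orderings stabilize far below that
full problem size.

## Known limitations

* The statistics presume the resolved tree (((P1,P2),P3),O); they are not
  applicable to other topologies, and misassignment of the outgroup
  corrupts polarization silently.
* Quantification is least reliable for P2→P3 gene flow (donor into
  archaic), where both `d_f` and `f_d` lose accuracy; the direction
  asymmetry of the $d_{xy}$ curves can flag this but the package does not
  automate directional inference.
* The jackknife Z rests on approximate normality of window statistics;
  windows with a handful of SNPs should be interpreted through their
  smoothed values and SNP counts, not their p-values alone.
* `read_vcf()` expects phased (or haploid) GT fields for haplotype-level
  analysis; random phasing of unphased heterozygotes is provided but is a
  coarse approximation for long-range LD-sensitive uses.
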