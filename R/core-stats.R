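#' Per-site pairwise nucleotide diversity between two populations
#'
#' At a biallelic site with derived-allele frequencies `px` and `py`, the
#' average pairwise difference between one haplotype from each population
#' is `px (1 - py) + (1 - px) py`.  This frequency form equals the mean
#' mismatch count over all pairs of haplotypes and is symmetric in its
#' arguments.
#'
#' @param px,py derived-allele frequencies in `[0, 1]` (vectorized).
#' @return per-site d_xy in `[0, 1]`.
#' @export
site_dxy <- function(px, py) px * (1 - py) + (1 - px) * py

#' Per-site nucleotide diversity within a population
#'
#' Frequency form `2 p (1 - p)`, with no small-sample correction, matching
#' the frequency form used for [site_dxy()] (an unbiased `n/(n-1)` variant
#' is available via `unbiased = TRUE` and a haplotype count `n`).
#'
#' @param p derived-allele frequency in `[0, 1]` (vectorized).
#' @param unbiased apply the `n/(n-1)` sample-size correction.
#' @param n haplotype count, required when `unbiased = TRUE`.
#' @return per-site within-population diversity in `[0, 0.5]`.
#' @export
site_pi <- function(p, unbiased = FALSE, n = NULL) {
  out <- 2 * p * (1 - p)
  if (unbiased) {
    if (is.null(n)) stop("`n` is required for the unbiased estimator")
    out <- out * n / (n - 1)
  }
  out
}

#' Laplace-smoothed derived-allele frequency
#'
#' Adds one derived and one ancestral allele to a population's sample:
#' `(derived_count + 1) / (n + 2)`.  In genome scans this is applied to P1
#' and P2 only, to keep small windows from producing extreme statistic
#' values when `p1` or `p2` is zero; d_xy terms are then recomputed from
#' the smoothed frequencies.
#'
#' @param derived_count number of derived alleles observed (vectorized).
#' @param n number of haplotypes sampled.
#' @return smoothed frequency in `(0, 1)`.
#' @export
laplace_smooth <- function(derived_count, n) {
  stopifnot(all(derived_count >= 0), all(derived_count <= n), all(n >= 1))
  (derived_count + 1) / (n + 2)
}

#' Frequency-weighted ABBA, BABA and BBAA site patterns
#'
#' The distance formulation of the two introgression patterns,
#' `ABBA_k = [p2 d13 - p1 d23 + p3 d12] (1 - p4) / 2` and
#' `BABA_k = [p1 d23 - p2 d13 + p3 d12] (1 - p4) / 2`, together with the
#' species-tree pattern weight `BBAA_k = p1 p2 (1 - p3) (1 - p4)`.
#' With strictly polarized data `p4 = 0` at every site.
#'
#' @param p1,p2,p3,p4 derived-allele frequencies (vectorized).
#' @return data.frame with columns `abba`, `baba`, `bbaa`.
#' @export
site_patterns <- function(p1, p2, p3, p4 = 0) {
  d12 <- site_dxy(p1, p2)
  d13 <- site_dxy(p1, p3)
  d23 <- site_dxy(p2, p3)
  half <- (1 - p4) / 2
  data.frame(abba = (p2 * d13 - p1 * d23 + p3 * d12) * half,
             baba = (p1 * d23 - p2 * d13 + p3 * d12) * half,
             bbaa = p1 * p2 * (1 - p3) * (1 - p4))
}

# Per-site numerator and denominators shared by all four window statistics.
# `laplace` replaces p1 and p2 by their Laplace-smoothed versions (counts
# c1/n1 and c2/n2 are then required) before any distance is formed.
site_terms <- function(freqs, laplace = FALSE) {
  p1 <- freqs$p1
  p2 <- freqs$p2
  if (laplace) {
    if (is.null(freqs$c1) || is.null(freqs$n1))
      stop("Laplace smoothing needs allele counts (columns c1, n1, c2, n2)")
    p1 <- laplace_smooth(freqs$c1, freqs$n1)
    p2 <- laplace_smooth(freqs$c2, freqs$n2)
  }
  p3 <- freqs$p3
  d12 <- site_dxy(p1, p2)
  d13 <- site_dxy(p1, p3)
  d23 <- site_dxy(p2, p3)
  pD <- pmax(p2, p3)            # ties resolve to either; all terms coincide
  d1D <- site_dxy(p1, pD)
  piD <- site_pi(pD)
  list(num    = p2 * d13 - p1 * d23,
       den_D  = p3 * d12,
       den_fhom = p3 * d13 - p1 * site_pi(p3),
       den_fd = pD * d1D - p1 * piD,
       den_df = p2 * d13 + p1 * d23)
}

ratio_or_na <- function(num, den) if (den == 0) NaN else num / den

#' Patterson's D in its distance formulation
#'
#' `D = sum(p2 d13 - p1 d23) / sum(p3 d12)` over the sites of a window.
#' Equals (ABBA - BABA) / (ABBA + BABA) of the classical formulation and
#' lies in `[-1, 1]` when defined.
#'
#' @param freqs site-frequency table from [site_frequencies()].
#' @param laplace smooth p1 and p2 first (see [laplace_smooth()]).
#' @return scalar D; `NaN` when the denominator is zero (e.g. a window of
#'   BBAA-only sites).
#' @export
patterson_d <- function(freqs, laplace = FALSE) {
  tm <- site_terms(freqs, laplace)
  ratio_or_na(sum(tm$num), sum(tm$den_D))
}

#' Green et al.'s f_hom admixture-fraction estimator
#'
#' `f_hom = sum(p2 d13 - p1 d23) / sum(p3 d13 - p1 pi3)`; assumes
#' introgression from P3 into P2, against which complete introgression
#' homogenizes the allele frequencies of P2 and P3 (f_hom = 1).
#'
#' @inheritParams patterson_d
#' @return scalar f_hom; `NaN` when undefined.
#' @export
f_hom <- function(freqs, laplace = FALSE) {
  tm <- site_terms(freqs, laplace)
  ratio_or_na(sum(tm$num), sum(tm$den_fhom))
}

#' Martin et al.'s f_d admixture-fraction estimator
#'
#' Same numerator as Patterson's D; the denominator substitutes, per site,
#' the donor proxy PD = the population (P2 or P3) with the higher
#' derived-allele frequency: `sum(pD d1D - p1 piD)`.
#'
#' @inheritParams patterson_d
#' @return scalar f_d; `NaN` when undefined.
#' @export
f_d <- function(freqs, laplace = FALSE) {
  tm <- site_terms(freqs, laplace)
  ratio_or_na(sum(tm$num), sum(tm$den_fd))
}

#' The distance fraction d_f
#'
#' `d_f = sum(p2 d13 - p1 d23) / sum(p2 d13 + p1 d23)`.  The numerator is
#' Patterson's D numerator; the denominator adds the species-tree (BBAA)
#' shared distance, so the statistic relates the distance difference caused
#' by introgression to the total shared distance to P3.  It is bounded in
#' `[-1, 1]` whenever defined, positive under P3<->P2 introgression and
#' negative under P3<->P1 introgression, and estimates the fraction of
#' introgression f.
#'
#' @inheritParams patterson_d
#' @return scalar d_f; `NaN` when the denominator is zero (mitigated by
#'   `laplace = TRUE` in scans).
#' @export
d_f <- function(freqs, laplace = FALSE) {
  tm <- site_terms(freqs, laplace)
  ratio_or_na(sum(tm$num), sum(tm$den_df))
}

#' All four window statistics with their accumulated sums
#'
#' @inheritParams patterson_d
#' @param window_start,window_end optional 0-based half-open window
#'   coordinates recorded in the result.
#' @return one-row data.frame with `D`, `f_hom`, `f_d`, `d_f`, the shared
#'   numerator sum `num`, the four denominator sums, `n_snps` and the
#'   window coordinates.
#' @export
window_stats <- function(freqs, laplace = FALSE,
                         window_start = NA_real_, window_end = NA_real_) {
  tm <- site_terms(freqs, laplace)
  num <- sum(tm$num)
  data.frame(
    window_start = window_start, window_end = window_end,
    n_snps = nrow(freqs),
    D     = ratio_or_na(num, sum(tm$den_D)),
    f_hom = ratio_or_na(num, sum(tm$den_fhom)),
    f_d   = ratio_or_na(num, sum(tm$den_fd)),
    d_f   = ratio_or_na(num, sum(tm$den_df)),
    num = num,
    den_D = sum(tm$den_D), den_fhom = sum(tm$den_fhom),
    den_fd = sum(tm$den_fd), den_df = sum(tm$den_df))
}

#' Mean pairwise distances between the three ingroup populations
#'
#' Averages of the per-site distances d_12, d_13 and d_23 over a region,
#' reported per base pair of the region's length (monomorphic sites
#' contribute zero distance).  These are polarization-free quantities.
#'
#' @param freqs site-frequency table.
#' @param length_bp region length used as the per-bp denominator; when
#'   `NULL` the raw per-variant-site means are returned.
#' @return named numeric vector `c(d12, d13, d23)`.
#' @export
pairwise_dxy <- function(freqs, length_bp = NULL) {
  s <- c(d12 = sum(site_dxy(freqs$p1, freqs$p2)),
         d13 = sum(site_dxy(freqs$p1, freqs$p3)),
         d23 = sum(site_dxy(freqs$p2, freqs$p3)))
  if (is.null(length_bp)) s / max(nrow(freqs), 1) else s / length_bp
}
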