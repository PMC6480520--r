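#' Window-based genome scan
#'
#' Tiles the region `[region_start, region_end)` with windows of
#' `width_bp` every `step_bp` (consecutive tiling when `width_bp ==
#' step_bp`, the 50 kb layout of chromosome scans) and computes the four
#' statistics per window.  Windows without usable SNPs carry `NaN`
#' statistics and `n_snps = 0`.  Laplace smoothing of p1/p2 is on by
#' default here, as recommended for genomic scans where small windows
#' otherwise produce extreme values.
#'
#' @param x a polarized [hap_matrix()] or a site-frequency table from
#'   [site_frequencies()].
#' @param width_bp,step_bp window width and step (bp); `width_bp >=
#'   step_bp >= 1`.
#' @param smooth apply Laplace smoothing to p1 and p2.
#' @param region_start,region_end scanned interval (0-based half-open);
#'   defaults to `0` and the smallest multiple of `step_bp` covering the
#'   last site.
#' @return a `scan_result`: data.frame of per-window rows from
#'   [window_stats()].
#' @export
window_scan <- function(x, width_bp, step_bp = width_bp, smooth = TRUE,
                        region_start = 0, region_end = NULL) {
  stopifnot(width_bp >= step_bp, step_bp >= 1)
  freqs <- if (inherits(x, "hap_matrix")) site_frequencies(x) else x
  if (is.null(region_end)) {
    last <- if (nrow(freqs)) max(freqs$position) else region_start
    region_end <- region_start +
      ceiling(max(last + 1 - region_start, width_bp) / step_bp) * step_bp
  }
  starts <- seq(region_start, region_end - width_bp, by = step_bp)
  rows <- lapply(starts, function(s0) {
    inw <- freqs$position >= s0 & freqs$position < s0 + width_bp
    window_stats(freqs[inw, , drop = FALSE], laplace = smooth,
                 window_start = s0, window_end = s0 + width_bp)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "smooth") <- smooth
  class(out) <- c("scan_result", class(out))
  out
}

# Delete-one-block estimates of a ratio statistic: block j removed from
# the pooled numerator/denominator sums.
delete_one_estimates <- function(num, den) {
  tn <- sum(num); td <- sum(den)
  ifelse(td - den == 0, NaN, (tn - num) / (td - den))
}

#' Weighted block jackknife Z-values for scan windows
#'
#' Blocks default to the scan windows themselves.  The pooled ratio
#' estimate over all blocks is jackknifed with the weighted delete-one
#' formula of Busing et al. (block weights proportional to SNP counts,
#' `weights = "snp"`; `"equal"` reduces to the standard delete-one
#' jackknife).  The resulting variance of the pooled estimate is rescaled
#' to the block level, `SE_j = sqrt(h_j) * SE(pooled)` with `h_j =
#' n/m_j`, giving each window a standard error on the scale of a single
#' window's statistic, and `Z_j = (theta_j - null) / SE_j`.
#'
#' Two null hypotheses are supported: `null = "zero"` tests each window
#' against no introgression, and `null = "mean"` tests windows inside
#' `region` against the pooled estimate of that region (the
#' inside-the-inversion test).
#'
#' @param scan a `scan_result` from [window_scan()].
#' @param statistic which window statistic to test (default `"d_f"`).
#' @param null `"zero"` or `"mean"`.
#' @param region `c(start, end)` bp; with `null = "mean"`, windows whose
#'   start lies in the region are tested against the region's pooled
#'   statistic (other windows keep the zero null).
#' @param weights `"snp"` or `"equal"`.
#' @param blocks optional integer block id per window; defaults to one
#'   block per window.
#' @return the scan with columns `se`, `Z`, `p` (two-sided normal) and
#'   `q` ([bh_fdr()]) appended; jackknife details (pooled estimate,
#'   delete-one estimates, pooled SE) attached as attribute `jackknife`.
#' @export
jackknife_z <- function(scan, statistic = "d_f", null = c("zero", "mean"),
                        region = NULL, weights = c("snp", "equal"),
                        blocks = NULL) {
  null <- match.arg(null)
  weights <- match.arg(weights)
  den_col <- switch(statistic, d_f = "den_df", D = "den_D",
                    f_d = "den_fd", f_hom = "den_fhom",
                    stop("unknown statistic: ", statistic))
  if (is.null(blocks)) blocks <- seq_len(nrow(scan))
  tap <- function(v) {
    out <- tapply(v, blocks, sum)
    stats::setNames(as.numeric(out), names(out))
  }
  bnum <- tap(scan$num)
  bden <- tap(scan[[den_col]])
  bm <- tap(scan$n_snps)
  use <- bm > 0
  if (sum(use) < 2) stop("need at least 2 non-empty jackknife blocks")
  bnum <- bnum[use]; bden <- bden[use]; bm <- bm[use]
  g <- length(bm)
  n <- sum(bm)
  theta <- sum(bnum) / sum(bden)
  loo <- delete_one_estimates(bnum, bden)
  h <- n / bm
  theta_J <- g * theta - sum((1 - bm / n) * loo)
  ps <- h * theta - (h - 1) * loo
  var_pooled <- mean((ps - theta_J)^2 / (h - 1))
  se_pooled <- sqrt(var_pooled)
  # map block-level SE back onto windows
  bl_of <- match(as.character(blocks), names(bm))
  se_w <- sqrt(h)[bl_of] * se_pooled
  stat_w <- scan[[statistic]]
  null_w <- rep(0, nrow(scan))
  if (null == "mean") {
    if (is.null(region)) stop("null = 'mean' requires a region")
    inside <- scan$window_start >= region[1] & scan$window_start < region[2]
    if (!any(inside)) stop("no windows inside the region")
    null_w[inside] <- sum(scan$num[inside]) / sum(scan[[den_col]][inside])
  }
  Z <- (stat_w - null_w) / se_w
  Z[!is.finite(Z)] <- NA_real_
  if (se_pooled == 0) {
    warning("jackknife variance is zero (statistic constant across blocks); Z undefined")
    Z[] <- NA_real_
  }
  scan$se <- se_w
  scan$Z <- Z
  scan$p <- 2 * stats::pnorm(-abs(Z))
  scan$q <- bh_fdr(scan$p)
  attr(scan, "jackknife") <- list(statistic = statistic, pooled = theta,
                                  loo = loo, se_pooled = se_pooled,
                                  weights = weights, null = null,
                                  blocks_used = g)
  scan
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment (monotone, capped at
#' 1); `NA`s are passed through.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return vector of q-values.
#' @export
bh_fdr <- function(p) stats::p.adjust(p, method = "BH")

#' Significant scan windows
#'
#' @param scan output of [jackknife_z()].
#' @param alpha_levels significance tiers, strictest reported per window.
#' @param statistic column reported in the table.
#' @return data.frame with one row per window with `q` below the loosest
#'   level: coordinates, statistic value, `Z`, `q` and `tier` (the
#'   strictest level passed).
#' @export
call_outliers <- function(scan, alpha_levels = c(0.05, 0.01),
                          statistic = "d_f") {
  alpha_levels <- sort(alpha_levels, decreasing = TRUE)
  hit <- !is.na(scan$q) & scan$q < alpha_levels[1]
  out <- data.frame(window_start = scan$window_start[hit],
                    window_end = scan$window_end[hit],
                    value = scan[[statistic]][hit],
                    Z = scan$Z[hit], q = scan$q[hit])
  out$tier <- vapply(out$q, function(q) min(alpha_levels[alpha_levels > q]),
                     numeric(1))
  names(out)[names(out) == "value"] <- statistic
  rownames(out) <- NULL
  out
}

#' Write scan results as TSV and significant windows as BED
#'
#' @param scan output of [jackknife_z()].
#' @param prefix output path prefix; writes `<prefix>.tsv` and (when
#'   significance columns are present) `<prefix>.sig.bed`.
#' @param alpha q-value threshold for the BED track.
#' @param chrom chromosome name used in the BED file.
#' @return invisibly, the paths written.
#' @export
write_scan <- function(scan, prefix, alpha = 0.05, chrom = "chr") {
  tsv <- paste0(prefix, ".tsv")
  utils::write.table(as.data.frame(scan), tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- tsv
  if ("q" %in% names(scan)) {
    hit <- !is.na(scan$q) & scan$q < alpha
    bed <- data.frame(chrom = rep(chrom, sum(hit)),
                      start = format(scan$window_start[hit], scientific = FALSE, trim = TRUE),
                      end = format(scan$window_end[hit], scientific = FALSE, trim = TRUE))
    bedp <- paste0(prefix, ".sig.bed")
    utils::write.table(bed, bedp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths <- c(paths, bedp)
  }
  invisible(paths)
}
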