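#' Accuracy metrics for an admixture-fraction estimator
#'
#' Scores per-locus estimates against the true simulated fraction with the
#' three standard measures: adjusted R-squared from the ordinary
#' least-squares fit of the estimate on the true fraction ("goodness of
#' fit"), the sum of squares due to lack of fit (squared distances from
#' each fraction's mean estimate to the true fraction, weighted by group
#' size) reported divided by the per-fraction sample size, and the pure
#' error sum of squares (squared distances of each estimate from its
#' fraction's mean).  Undefined estimates (`NaN`/`NA`, from zero
#' denominators) are excluded with a logged count.
#'
#' @param f_true vector of true introgression fractions.
#' @param value vector of per-locus statistic values.
#' @param n_per_f divisor for SSLF (the per-fraction sample size; defaults
#'   to the mean group size after exclusions).
#' @param r2 `"regression"` (default; OLS of value on f) or `"identity"`
#'   (R-squared about the 1:1 line `value = f`).
#' @return list with `adj_R2`, `SSLF_over_n`, `SSLF_raw`, `SSPE`,
#'   `n_used`, `n_dropped`.
#' @export
fit_metrics <- function(f_true, value, n_per_f = NULL,
                        r2 = c("regression", "identity")) {
  r2 <- match.arg(r2)
  ok <- is.finite(value)
  n_dropped <- sum(!ok)
  f_true <- f_true[ok]; value <- value[ok]
  if (!length(value)) stop("all estimates are undefined")
  if (length(unique(f_true)) < 2)
    stop("need at least 2 distinct true fractions")
  grp <- factor(f_true)
  ybar <- tapply(value, grp, mean)
  nj <- tapply(value, grp, length)
  fj <- as.numeric(levels(grp))
  sslf <- sum(nj * (ybar - fj)^2)
  sspe <- sum((value - ybar[grp])^2)
  if (is.null(n_per_f)) n_per_f <- mean(nj)
  adj <- if (r2 == "regression") {
    summary(stats::lm(value ~ f_true))$adj.r.squared
  } else {
    n <- length(value)
    r2raw <- 1 - sum((value - f_true)^2) / sum((value - mean(value))^2)
    1 - (1 - r2raw) * (n - 1) / (n - 2)
  }
  list(adj_R2 = adj, SSLF_over_n = sslf / n_per_f, SSLF_raw = sslf,
       SSPE = sspe, n_used = length(value), n_dropped = n_dropped)
}

#' Accuracy experiment over an introgression-fraction grid
#'
#' Simulates `reps` loci for every fraction in `f_values`, computes the
#' whole-locus statistics and scores each against the true fraction with
#' [fit_metrics()] (the three-metric layout of the simulation study).
#'
#' @param config a [sim_config()].
#' @param f_values grid of fractions (default `seq(0, 1, 0.1)`).
#' @param reps loci per fraction (default 100).
#' @param seed master seed.
#' @param statistics statistics to score.
#' @return list of class `eval_report`: `metrics` (data.frame, one row per
#'   statistic), `grid` (the per-locus table), `config`, `seed`.
#' @export
run_accuracy_experiment <- function(config, f_values = seq(0, 1, by = 0.1),
                                    reps = 100, seed = NULL,
                                    statistics = c("D", "f_d", "d_f")) {
  grid <- simulate_grid(config, f_values, reps, seed = seed)
  metrics <- do.call(rbind, lapply(statistics, function(st) {
    m <- fit_metrics(grid$f, grid[[st]], n_per_f = reps)
    data.frame(statistic = st, adj_R2 = m$adj_R2,
               SSLF_over_n = m$SSLF_over_n, SSPE = m$SSPE,
               n_used = m$n_used, n_dropped = m$n_dropped)
  }))
  structure(list(metrics = metrics, grid = grid, config = config,
                 seed = seed, f_values = f_values, reps = reps),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("accuracy experiment: %d fractions x %d loci (%s)\n",
              length(x$f_values), x$reps, x$config$direction))
  print(x$metrics, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Detection experiment: ROC AUC per statistic
#'
#' Simulates neutral and introgressed loci and measures each statistic's
#' ability to rank introgressed above neutral loci as the area under the
#' ROC curve (rank-based, tie-aware, via pROC).  Loci with an undefined
#' statistic are excluded from that statistic's ROC with a logged count.
#'
#' @param config [sim_config()] for the introgressed class (its `f` > 0).
#' @param n_neutral,n_introgressed loci per class.
#' @param seed master seed.
#' @param statistics statistics to score.
#' @return list with `auc` (named vector), `n_dropped` (named vector) and
#'   the labeled per-locus table `set`.
#' @export
run_detection_experiment <- function(config, n_neutral, n_introgressed,
                                     seed = NULL,
                                     statistics = c("D", "f_d", "d_f")) {
  set <- simulate_detection_set(config, config, n_neutral, n_introgressed,
                                seed = seed)
  if (length(unique(set$introgressed)) < 2)
    stop("need both neutral and introgressed loci")
  auc <- numeric(0); drp <- integer(0)
  for (st in statistics) {
    v <- set[[st]]
    ok <- is.finite(v)
    r <- pROC::roc(response = set$introgressed[ok], predictor = v[ok],
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
    auc[st] <- as.numeric(pROC::auc(r))
    drp[st] <- sum(!ok)
  }
  list(auc = auc, n_dropped = drp, set = set)
}

#' Pairwise-distance response to the introgression fraction
#'
#' Monte-Carlo means of the per-bp pairwise distances d_12, d_13 and d_23
#' as a function of the simulated fraction f, with the fitted slope of
#' each mean distance on f.  Gene flow from P3 into P2 erodes d_23 while
#' leaving d_13 flat; from P2 into P3 it erodes d_23 while leaving d_12
#' flat — the asymmetry that carries directional signal.
#'
#' @param config a [sim_config()] (its `direction` is used).
#' @param f_values grid of fractions.
#' @param reps loci per fraction.
#' @param seed master seed.
#' @return list with `means` (data.frame: f, d12, d13, d23) and `slopes`
#'   (data.frame: distance, slope, se, t from OLS of the per-f means on f).
#' @export
dxy_vs_f_curves <- function(config, f_values = seq(0, 1, by = 0.1),
                            reps = 50, seed = NULL) {
  grid <- simulate_grid(config, f_values, reps, seed = seed)
  means <- aggregate(grid[, c("d12", "d13", "d23")],
                     by = list(f = grid$f), FUN = mean)
  slopes <- do.call(rbind, lapply(c("d12", "d13", "d23"), function(dn) {
    fit <- summary(stats::lm(means[[dn]] ~ means$f))$coefficients
    data.frame(distance = dn, slope = fit[2, 1], se = fit[2, 2],
               t = fit[2, 3])
  }))
  list(means = means, slopes = slopes, direction = config$direction)
}
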