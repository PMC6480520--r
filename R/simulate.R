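#' Four-taxon coalescent simulation configuration
#'
#' Describes the demography (((P1,P2),P3),O) with a single admixture
#' pulse, mirroring the classic ms + seq-gen pipeline.  Times are in units
#' of 4N generations; the baseline values are split times 1/2/3, a pulse
#' of fraction `f` at `t_gf = 0.1`, recombination `rho = 50` over a 5 kb
#' locus, and HKY substitutions with branch scale `s = 0.01` (about 1%
#' expected within-population diversity).
#'
#' @param f introgression fraction in `[0, 1]`.
#' @param direction `"P3->P2"` (baseline), `"P2->P3"` or `"P3->P1"`;
#'   forward-time direction of the pulse.
#' @param t12,t123,t123O split times P12, P123, P123O (4N units);
#'   `t12 <= t123 <= t123O` (equality of `t12` and `t123` gives the
#'   "1-1-3" trident history).
#' @param t_gf time of the gene-flow pulse, `0 < t_gf < t12`.
#' @param rho population recombination parameter 4Nr for the whole locus.
#' @param L locus length in bp.
#' @param s branch scaling factor: substitutions per site per 4N
#'   generations.
#' @param samples_per_pop haplotypes sampled per population (>= 2).
#' @param n12,n123 relative sizes of the (P1,P2) and (P1,P2,P3) ancestral
#'   populations.
#' @param model `"hky"` (sequence simulation, variant columns extracted
#'   and polarized by the outgroup downstream) or `"infinite_sites"`
#'   (0/1 sites at matched expected density, true ancestral state known).
#' @param kappa,base_freq HKY transition/transversion ratio and base
#'   frequencies (unspecified nuisance parameters of the pipeline;
#'   defaults kappa = 2, equal frequencies).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(f = 0.1, direction = c("P3->P2", "P2->P3", "P3->P1"),
                       t12 = 1, t123 = 2, t123O = 3, t_gf = 0.1,
                       rho = 50, L = 5000, s = 0.01, samples_per_pop = 8,
                       n12 = 1, n123 = 1,
                       model = c("hky", "infinite_sites"),
                       kappa = 2, base_freq = rep(0.25, 4)) {
  direction <- match.arg(direction)
  model <- match.arg(model)
  if (!(f >= 0 && f <= 1)) stop("f must be in [0, 1]")
  if (!(t_gf > 0 && t_gf < t12)) stop("need 0 < t_gf < t12")
  if (!(t12 <= t123 && t123 <= t123O)) stop("need t12 <= t123 <= t123O")
  if (rho < 0) stop("rho must be >= 0")
  if (L < 1) stop("L must be >= 1")
  if (samples_per_pop < 2) stop("samples_per_pop must be >= 2")
  if (n12 <= 0 || n123 <= 0) stop("ancestral sizes must be positive")
  if (length(base_freq) != 4 || any(base_freq <= 0))
    stop("base_freq must be 4 positive values")
  structure(list(f = f, direction = direction, t12 = t12, t123 = t123,
                 t123O = t123O, t_gf = t_gf, rho = rho, L = as.integer(L),
                 s = s, samples_per_pop = as.integer(samples_per_pop),
                 n12 = n12, n123 = n123, model = model, kappa = kappa,
                 base_freq = base_freq / sum(base_freq)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: f=%.3g %s at t_gf=%.3g | splits %.3g/%.3g/%.3g x4N | rho=%.3g L=%d s=%.3g | %d haplotypes/pop | %s\n",
    x$f, x$direction, x$t_gf, x$t12, x$t123, x$t123O, x$rho, x$L, x$s,
    x$samples_per_pop, x$model))
  invisible(x)
}

# Event table for the ARG simulator.  Backwards in time the forward pulse
# X -> Y (donor X) moves each lineage of Y into X with probability f at
# t_gf; population indices are 0-based (P1=0, P2=1, P3=2, O=3).
sim_events <- function(cfg) {
  ev <- list()
  if (cfg$f > 0) {
    pulse <- switch(cfg$direction,
                    "P3->P2" = c(a = 1L, b = 2L),
                    "P2->P3" = c(a = 2L, b = 1L),
                    "P3->P1" = c(a = 0L, b = 2L))
    ev[[length(ev) + 1]] <- list(time = cfg$t_gf, type = 1L,
                                 a = pulse[["a"]], b = pulse[["b"]], x = cfg$f)
  }
  ev[[length(ev) + 1]] <- list(time = cfg$t12, type = 0L, a = 1L, b = 0L, x = 0)
  ev[[length(ev) + 1]] <- list(time = cfg$t12, type = 2L, a = 0L, b = 0L, x = cfg$n12)
  ev[[length(ev) + 1]] <- list(time = cfg$t123, type = 0L, a = 2L, b = 0L, x = 0)
  ev[[length(ev) + 1]] <- list(time = cfg$t123, type = 2L, a = 0L, b = 0L, x = cfg$n123)
  ev[[length(ev) + 1]] <- list(time = cfg$t123O, type = 0L, a = 3L, b = 0L, x = 0)
  ev <- do.call(rbind, lapply(ev, as.data.frame))
  ev[order(ev$time), , drop = FALSE]   # stable: ties keep construction order
}

# Eigen-decomposition of the symmetrized, rate-1-normalized HKY generator.
hky_eigen <- function(kappa, base_freq) {
  pi4 <- base_freq / sum(base_freq)
  # base order A, C, G, T; transitions A<->G, C<->T
  Q <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    ti <- (i + j == 4 && abs(i - j) == 2) || (i + j == 6 && abs(i - j) == 2)
    Q[i, j] <- pi4[j] * if (ti) kappa else 1
  }
  diag(Q) <- -rowSums(Q)
  rate <- -sum(pi4 * diag(Q))
  Q <- Q / rate
  S <- diag(sqrt(pi4)) %*% Q %*% diag(1 / sqrt(pi4))
  S <- (S + t(S)) / 2
  eg <- eigen(S, symmetric = TRUE)
  list(V = eg$vectors, lambda = eg$values, pi = pi4)
}

#' HKY transition probability matrix
#'
#' Probability of each base-to-base change over a branch of length `tau`
#' substitutions per site, for the model in a [sim_config()].  Exposed
#' mainly so the substitution machinery can be checked directly.
#'
#' @param tau branch length in expected substitutions per site.
#' @param kappa transition/transversion rate ratio.
#' @param base_freq equilibrium base frequencies (A, C, G, T).
#' @return 4x4 stochastic matrix, rows = ancestral base.
#' @export
hky_transition <- function(tau, kappa = 2, base_freq = rep(0.25, 4)) {
  h <- hky_eigen(kappa, base_freq)
  P <- diag(1 / sqrt(h$pi)) %*% h$V %*% diag(exp(h$lambda * tau)) %*%
    t(h$V) %*% diag(sqrt(h$pi))
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Simulate one locus under the four-taxon demography
#'
#' Draws genealogies under the structured coalescent with recombination
#' and a single admixture pulse, lays mutations on them under the
#' configured substitution model, and returns the biallelic variant sites
#' as a [hap_matrix()].  Under the `"hky"` model the matrix is
#' unpolarized (allele coding relative to the observed alleles, exactly as
#' sequence data would present) and should be passed through [polarize()];
#' under `"infinite_sites"` allele 1 is the derived allele by
#' construction.
#'
#' @param config a [sim_config()].
#' @param return_alignment also return the full nucleotide alignment
#'   (`"hky"` model only), as a character matrix haplotypes x sites.
#' @return a `hap_matrix` (with attribute `true_anc` giving, per site, the
#'   allele code of the true ancestral base, or -1 where the ancestral
#'   allele was lost); if `return_alignment = TRUE`, a list with elements
#'   `hap` and `alignment`.
#' @export
simulate_locus <- function(config, return_alignment = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  ev <- sim_events(config)
  arg <- .sim_arg_cpp(rep(config$samples_per_pop, 4), config$L, config$rho,
                      ev$time, ev$type, ev$a, ev$b, ev$x, 4L)
  pops <- block_pops(rep(config$samples_per_pop, 4))
  if (config$model == "infinite_sites") {
    mut <- .mutate_infinite_sites_cpp(arg$node_time, arg$left, arg$right,
                                      arg$parent, arg$child, arg$n_samples,
                                      config$L, config$s)
    keep <- !duplicated(mut$positions)
    hm <- hap_matrix(mut$geno[keep, , drop = FALSE], mut$positions[keep],
                     pops, polarized = TRUE, source = "sim/infinite_sites")
    attr(hm, "true_anc") <- rep(0L, sum(keep))
    if (return_alignment) stop("alignments are only produced under the HKY model")
    return(hm)
  }
  h <- hky_eigen(config$kappa, config$base_freq)
  sq <- .sim_sequence_hky_cpp(arg$node_time, arg$left, arg$right, arg$parent,
                              arg$child, arg$n_samples, config$L, config$s,
                              h$V, h$lambda, h$pi)
  v <- .extract_variants_cpp(sq$align, sq$anc)
  hm <- hap_matrix(v$geno, v$positions, pops, polarized = FALSE,
                   source = "sim/hky",
                   dropped = c(multiallelic = v$n_multiallelic))
  attr(hm, "true_anc") <- v$anc_code
  if (return_alignment) {
    bases <- c("A", "C", "G", "T")
    aln <- matrix(bases[sq$align + 1L], nrow = nrow(sq$align))
    rownames(aln) <- sprintf("s%02d_%s", seq_len(nrow(aln)), pops)
    return(list(hap = hm, alignment = aln))
  }
  hm
}

# The statistics pipeline applied to one simulated locus: polarize by the
# outgroup (strict), build frequencies, compute the whole-locus window
# statistics and the per-bp pairwise distances.
locus_summary <- function(hm, config, laplace = FALSE) {
  if (!hm$polarized) hm <- polarize(hm, "strict")
  fr <- site_frequencies(hm)
  ws <- window_stats(fr, laplace = laplace,
                     window_start = 0, window_end = config$L)
  dx <- pairwise_dxy(fr, length_bp = config$L)
  cbind(ws, d12 = dx[["d12"]], d13 = dx[["d13"]], d23 = dx[["d23"]])
}

#' Simulate a grid of introgression fractions
#'
#' `reps` independent loci for every value of `f`, with the whole-locus
#' statistics (D, f_hom, f_d, d_f) and per-bp pairwise distances computed
#' for each locus.  Reproducible given `seed`: per-locus seeds are drawn
#' deterministically from the master seed.
#'
#' @param config a [sim_config()]; its `f` is overridden by `f_values`.
#' @param f_values vector of introgression fractions (canonical grid
#'   `seq(0, 1, 0.1)`).
#' @param reps loci per fraction.
#' @param seed master seed (integer).
#' @param keep_matrices also return the simulated `hap_matrix` objects.
#' @return data.frame with columns `f`, `rep`, the statistics and distance
#'   columns of [window_stats()]; if `keep_matrices`, the matrices are
#'   attached as attribute `matrices` (a list indexed like the rows).
#' @export
simulate_grid <- function(config, f_values = seq(0, 1, by = 0.1), reps = 100,
                          seed = NULL, keep_matrices = FALSE) {
  stopifnot(reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", length(f_values) * reps)
  mats <- if (keep_matrices) vector("list", length(out)) else NULL
  i <- 0
  for (fv in f_values) {
    cfg <- config
    cfg$f <- fv
    if (fv == 0) cfg$f <- 0
    for (r in seq_len(reps)) {
      i <- i + 1
      hm <- simulate_locus(cfg)
      out[[i]] <- cbind(data.frame(f = fv, rep = r), locus_summary(hm, cfg))
      if (keep_matrices) mats[[i]] <- hm
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (keep_matrices) attr(res, "matrices") <- mats
  res
}

#' Simulate a labeled detection set
#'
#' Neutral loci (`f = 0`) and introgressed loci under the given
#' configuration, labeled for ROC analysis.
#'
#' @param config_neutral,config_introgressed [sim_config()]s for the two
#'   classes (the neutral one is forced to `f = 0`).
#' @param n_neutral,n_introgressed loci per class (full scale: 10000 and
#'   1000).
#' @param seed master seed.
#' @return data.frame of per-locus statistics with a logical column
#'   `introgressed`.
#' @export
simulate_detection_set <- function(config_neutral, config_introgressed,
                                   n_neutral, n_introgressed, seed = NULL) {
  stopifnot(n_neutral >= 1, n_introgressed >= 1)
  if (!is.null(seed)) set.seed(seed)
  cfg0 <- config_neutral
  cfg0$f <- 0
  sim1 <- function(cfg, lab, r) {
    hm <- simulate_locus(cfg)
    cbind(data.frame(introgressed = lab, rep = r), locus_summary(hm, cfg))
  }
  out <- c(lapply(seq_len(n_neutral), function(r) sim1(cfg0, FALSE, r)),
           lapply(seq_len(n_introgressed),
                  function(r) sim1(config_introgressed, TRUE, r)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a chromosome as a chain of independent loci
#'
#' Concatenates independent simulated loci into one long [hap_matrix()]
#' with shifted coordinates (free recombination between loci), with an
#' optional introgressed tract: loci whose start falls inside
#' `tract` get `tract_f` instead of `config$f`.  Used to exercise the
#' genome-scan machinery on data with a known answer.
#'
#' @param config per-locus [sim_config()] (its `L` is the locus size).
#' @param n_loci number of consecutive loci.
#' @param tract `c(start, end)` in bp (0-based half-open) or `NULL`.
#' @param tract_f introgression fraction inside the tract.
#' @param seed master seed.
#' @return a polarized `hap_matrix` spanning `n_loci * config$L` bp.
#' @export
simulate_chromosome <- function(config, n_loci, tract = NULL, tract_f = 0.8,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pieces <- vector("list", n_loci)
  pops <- block_pops(rep(config$samples_per_pop, 4))
  for (i in seq_len(n_loci)) {
    start <- (i - 1) * config$L
    cfg <- config
    if (!is.null(tract) && start >= tract[1] && start < tract[2])
      cfg$f <- tract_f
    hm <- simulate_locus(cfg)
    if (!hm$polarized) hm <- polarize(hm, "strict")
    hm$positions <- hm$positions + start
    pieces[[i]] <- hm
  }
  alle <- do.call(rbind, lapply(pieces, function(h) h$alleles))
  posn <- do.call(c, lapply(pieces, function(h) h$positions))
  hap_matrix(alle, posn, pops, polarized = TRUE, source = "sim/chromosome")
}
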