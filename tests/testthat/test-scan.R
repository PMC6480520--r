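scan_fixture <- function() {
  # 10 windows of 100 bp; ABBA-rich tract in windows 5-6, background with
  # balanced ABBA/BABA plus BBAA filler
  set.seed(123)
  pat_bg <- rbind(c(0, 1, 1, 0), c(1, 0, 1, 0), c(1, 1, 0, 0), c(1, 1, 0, 0))
  rows <- list()
  for (w in 0:9) {
    base <- if (w %in% c(4, 5)) matrix(rep(c(0, 1, 1, 0), 8), ncol = 4, byrow = TRUE)
    else pat_bg
    pos <- sort(sample(0:99, nrow(base))) + w * 100
    rows[[w + 1]] <- cbind(pos, base)
  }
  m <- do.call(rbind, rows)
  G <- matrix(0L, nrow(m), 8)
  for (p in 1:4) G[, (2 * p - 1):(2 * p)] <- m[, p + 1]
  hap_matrix(G, m[, 1], rep(c("P1", "P2", "P3", "O"), each = 2),
             polarized = TRUE, source = "fixture")
}

test_that("window_scan tiles the region and computes per-window statistics", {
  hm <- scan_fixture()
  sc <- window_scan(hm, width_bp = 100, step_bp = 100, smooth = FALSE)
  expect_equal(nrow(sc), 10)           # floor(span / width) consecutive tiles
  expect_equal(sc$window_start, seq(0, 900, by = 100))
  expect_equal(sum(sc$n_snps), nrow(hm$alleles))
  # tract windows carry the top d_f values
  expect_setequal(order(sc$d_f, decreasing = TRUE)[1:2], c(5, 6))
  # background windows: equal ABBA/BABA -> d_f = 0
  expect_equal(sc$d_f[1], 0)
})

test_that("an all-BBAA region gives d_f = 0 in every window and undefined D", {
  G <- matrix(rep(c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L), 12), ncol = 8, byrow = TRUE)
  hm <- hap_matrix(G, seq(5, 115, by = 10), rep(c("P1", "P2", "P3", "O"), each = 2),
                   polarized = TRUE)
  sc <- window_scan(hm, 40, 40, smooth = FALSE)
  expect_true(all(sc$d_f == 0))
  expect_true(all(is.nan(sc$D)))
})

test_that("windows without SNPs carry sentinel statistics", {
  hm <- scan_fixture()
  keep <- hm$positions < 300 | hm$positions >= 400   # empty window 4
  hm$alleles <- hm$alleles[keep, , drop = FALSE]
  hm$positions <- hm$positions[keep]
  sc <- window_scan(hm, 100, 100, smooth = FALSE, region_end = 1000)
  expect_equal(sc$n_snps[4], 0)
  expect_true(is.nan(sc$d_f[4]))
})

test_that("weighted jackknife matches a naive delete-one recomputation", {
  hm <- scan_fixture()
  fr <- site_frequencies(hm)
  sc <- window_scan(hm, 100, 100, smooth = TRUE)
  sc <- jackknife_z(sc, statistic = "d_f")
  jk <- attr(sc, "jackknife")
  # naive loop: recompute the pooled statistic from the raw sites with each
  # window's sites deleted
  for (j in seq_len(nrow(sc))) {
    inw <- fr$position >= sc$window_start[j] & fr$position < sc$window_end[j]
    loo_naive <- d_f(fr[!inw, , drop = FALSE], laplace = TRUE)
    expect_equal(unname(jk$loo[j]), loo_naive, tolerance = 1e-10)
  }
  # naive Busing variance from the delete-one estimates
  m <- sc$n_snps; n <- sum(m); g <- length(m)
  theta <- d_f(fr, laplace = TRUE)
  h <- n / m
  theta_J <- g * theta - sum((1 - m / n) * jk$loo)
  ps <- h * theta - (h - 1) * jk$loo
  se_naive <- sqrt(mean((ps - theta_J)^2 / (h - 1)))
  expect_equal(jk$se_pooled, se_naive, tolerance = 1e-10)
  expect_equal(sc$Z, (sc$d_f - 0) / (sqrt(h) * se_naive), tolerance = 1e-10)
})

test_that("equal block weights reduce to the standard delete-one jackknife", {
  vals <- c(0.1, 0.3, -0.2, 0.25, 0.05)
  sc <- data.frame(window_start = 0:4 * 10, window_end = 1:5 * 10,
                   n_snps = rep(5L, 5), d_f = vals,
                   num = vals, den_df = rep(1, 5),
                   den_D = 1, den_fhom = 1, den_fd = 1)
  out <- jackknife_z(sc, statistic = "d_f")
  g <- 5
  theta <- sum(vals) / 5
  loo <- (sum(vals) - vals) / 4
  var_std <- (g - 1) / g * sum((loo - mean(loo))^2)
  expect_equal(attr(out, "jackknife")$se_pooled, sqrt(var_std), tolerance = 1e-12)
  expect_equal(out$se, rep(sqrt(g * var_std), g), tolerance = 1e-12)
})

test_that("degenerate jackknife cases are handled", {
  sc <- data.frame(window_start = 0:3 * 10, window_end = 1:4 * 10,
                   n_snps = rep(2L, 4), d_f = rep(0.5, 4),
                   num = rep(1, 4), den_df = rep(2, 4),
                   den_D = 1, den_fhom = 1, den_fd = 1)
  expect_warning(out <- jackknife_z(sc), "variance is zero")
  expect_true(all(is.na(out$Z)))
  expect_error(jackknife_z(sc[1, , drop = FALSE]), "at least 2")
})

test_that("the regional-mean null gives Z = 0 for a window at the regional mean", {
  hm <- scan_fixture()
  sc <- window_scan(hm, 100, 100, smooth = FALSE)
  out <- jackknife_z(sc, null = "mean", region = c(400, 600))
  # windows 5 and 6 are identical -> each equals the regional pooled value
  expect_equal(out$Z[5], 0)
  expect_equal(out$Z[6], 0)
  # outside the region the zero null still applies
  expect_equal(out$Z[1], sc$d_f[1] / out$se[1])
})

test_that("bh_fdr matches the hand step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(5)
  p <- runif(50)^2
  expect_equal(bh_fdr(p), stepup_bh(p), tolerance = 1e-12)
  # monotone in p
  o <- order(p)
  expect_true(all(diff(bh_fdr(p)[o]) >= -1e-12))
})

test_that("call_outliers reports nested significance tiers", {
  sc <- data.frame(window_start = 0:4 * 10, window_end = 1:5 * 10,
                   d_f = c(0.9, 0.5, 0.1, -0.8, 0),
                   Z = c(5, 2.5, 0.3, -4, 0),
                   q = c(0.001, 0.03, 0.9, 0.004, 1))
  out <- call_outliers(sc)
  expect_equal(out$window_start, c(0, 10, 30))
  expect_equal(out$tier, c(0.01, 0.05, 0.01))
  strict <- out[out$tier == 0.01, "window_start"]
  expect_true(all(strict %in% out$window_start))
  # nothing significant -> empty table
  sc$q <- 0.5
  expect_equal(nrow(call_outliers(sc)), 0)
})

test_that("write_scan emits a TSV and a BED of significant windows", {
  sc <- data.frame(window_start = c(0, 50000), window_end = c(50000, 100000),
                   n_snps = c(10L, 12L), d_f = c(0.8, 0.0),
                   num = c(1, 0), den_df = c(1.25, 1),
                   den_D = 1, den_fhom = 1, den_fd = 1,
                   se = c(0.1, 0.1), Z = c(8, 0), p = c(1e-15, 1),
                   q = c(2e-15, 1))
  prefix <- file.path(withr::local_tempdir(), "scan")
  paths <- write_scan(sc, prefix)
  expect_true(all(file.exists(paths)))
  bed <- utils::read.table(paths[2], sep = "\t")
  expect_equal(nrow(bed), 1)
  expect_equal(bed$V2, 0)
  expect_equal(bed$V3, 50000)
})
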