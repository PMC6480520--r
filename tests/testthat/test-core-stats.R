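test_that("site_dxy matches fixed examples and is symmetric", {
  expect_equal(site_dxy(1, 0), 1)
  expect_equal(site_dxy(0.5, 0.5), 0.5)
  # brute-force oracle: 4 haplotypes per population, 1 vs 3 derived
  hx <- c(1, 0, 0, 0); hy <- c(1, 1, 1, 0)
  expect_equal(brute_dxy(hx, hy), 10 / 16)
  expect_equal(site_dxy(0.25, 0.75), brute_dxy(hx, hy))
  expect_equal(site_dxy(0.3, 0.8), site_dxy(0.8, 0.3))
})

test_that("site_dxy equals mean pairwise mismatch for all achievable frequencies (n <= 8)", {
  for (nx in 2:8) for (ny in 2:8) {
    for (cx in 0:nx) for (cy in 0:ny) {
      hx <- rep(c(1L, 0L), c(cx, nx - cx))
      hy <- rep(c(1L, 0L), c(cy, ny - cy))
      expect_equal(site_dxy(cx / nx, cy / ny), brute_dxy(hx, hy),
                   tolerance = 1e-12)
    }
  }
})

test_that("site_pi matches examples and supports the unbiased variant", {
  expect_equal(site_pi(0), 0)
  expect_equal(site_pi(0.5), 0.5)
  expect_equal(site_pi(0.25), 0.375)
  expect_equal(site_pi(0.5, unbiased = TRUE, n = 8), 0.5 * 8 / 7)
})

test_that("laplace_smooth applies (count + 1) / (n + 2)", {
  expect_equal(laplace_smooth(0, 8), 0.1)
  expect_equal(laplace_smooth(8, 8), 0.9)
  expect_equal(laplace_smooth(4, 8), 0.5)
  # symmetry preserved around 0.5
  expect_equal(laplace_smooth(3, 8) + laplace_smooth(5, 8), 1)
  expect_error(laplace_smooth(9, 8))
})

test_that("site pattern weights recover the fixed ABBA/BABA/BBAA configurations", {
  ab <- site_patterns(0, 1, 1, 0)
  expect_equal(unlist(ab), c(abba = 1, baba = 0, bbaa = 0))
  ba <- site_patterns(1, 0, 1, 0)
  expect_equal(unlist(ba), c(abba = 0, baba = 1, bbaa = 0))
  bb <- site_patterns(1, 1, 0, 0)
  expect_equal(unlist(bb)[["bbaa"]], 1)
  # ABBA + BABA collapses to p3 * d12 (the D denominator)
  p <- freqs_table(p1 = c(.2, .7), p2 = c(.9, .1), p3 = c(.5, .8))
  w <- site_patterns(p$p1, p$p2, p$p3, p$p4)
  expect_equal(w$abba + w$baba, p$p3 * site_dxy(p$p1, p$p2))
})

test_that("patterson_d matches its fixed-site examples", {
  expect_equal(patterson_d(freqs_table(0, 1, 1)), 1)
  # BBAA-only window: denominator is zero, statistic undefined
  expect_true(is.nan(patterson_d(freqs_table(c(1, 1), c(1, 1), c(0, 0)))))
  # equal ABBA and BABA counts cancel
  fr <- freqs_table(p1 = c(0, 0, 0, 1, 1, 1), p2 = c(1, 1, 1, 0, 0, 0),
                    p3 = 1)
  expect_equal(patterson_d(fr), 0)
})

test_that("D equals literal pattern counting on fixed-site windows", {
  pat <- all_fixed_patterns()
  # every single fixed pattern
  for (i in seq_len(nrow(pat))) {
    one <- pat[i, , drop = FALSE]
    fr <- freqs_from_patterns(one)
    fr <- fr[fr$p4 == 0, , drop = FALSE]  # polarized data: p4 = 0
    if (!nrow(fr)) next
    expect_equal(patterson_d(fr), pattern_count_D(one), tolerance = 1e-12)
  }
  # random mixtures of fixed patterns
  set.seed(42)
  pol <- pat[pat[, 4] == 0, , drop = FALSE]
  for (r in 1:1000) {
    rows <- sample(nrow(pol), size = sample(1:30, 1), replace = TRUE)
    mix <- pol[rows, , drop = FALSE]
    got <- patterson_d(freqs_from_patterns(mix))
    want <- pattern_count_D(mix)
    if (is.nan(want)) expect_true(is.nan(got)) else
      expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("f_hom matches examples and the homogenization limit", {
  expect_equal(f_hom(freqs_table(0, 1, 1)), 1)
  expect_equal(f_hom(freqs_table(0, 0, 1)), 0)
  # complete homogenization: p2 == p3 everywhere, unadmixed P1
  set.seed(7)
  p3 <- runif(40)
  fr <- freqs_table(p1 = rep(0, 40), p2 = p3, p3 = p3)
  expect_equal(f_hom(fr), 1, tolerance = 1e-12)
  # per-site algebra: d23 reduces to pi3 when p2 = p3
  expect_equal(site_dxy(p3, p3), site_pi(p3))
})

test_that("f_d matches examples and is invariant to the PD tie-break", {
  expect_equal(f_d(freqs_table(0, 1, 1)), 1)
  # substitution of the higher derived frequency: pD = max(0.5, 1) = 1
  expect_equal(f_d(freqs_table(0, 0.5, 1)), 0.5)
  # ties p2 == p3: both choices of PD give identical terms
  set.seed(8)
  p <- runif(20)
  fr <- freqs_table(p1 = runif(20, 0, 0.3), p2 = p, p3 = p)
  pD <- fr$p2
  den_manual <- sum(pD * site_dxy(fr$p1, pD) - fr$p1 * site_pi(pD))
  num <- sum(fr$p2 * site_dxy(fr$p1, fr$p3) - fr$p1 * site_dxy(fr$p2, fr$p3))
  expect_equal(f_d(fr), num / den_manual, tolerance = 1e-12)
})

test_that("d_f matches its single-site examples", {
  expect_equal(d_f(freqs_table(0, 1, 1)), 1)
  expect_equal(d_f(freqs_table(1, 0, 1)), -1)
  expect_equal(d_f(freqs_table(1, 1, 0)), 0)
})

test_that("d_f and D are bounded and antisymmetric under P1/P2 swap", {
  set.seed(9)
  for (r in 1:200) {
    k <- sample(1:25, 1)
    fr <- freqs_table(p1 = runif(k), p2 = runif(k), p3 = runif(k))
    v <- d_f(fr)
    if (is.finite(v)) expect_true(abs(v) <= 1 + 1e-12)
    D <- patterson_d(fr)
    if (is.finite(D)) expect_true(abs(D) <= 1 + 1e-12)
    sw <- fr; sw$p1 <- fr$p2; sw$p2 <- fr$p1
    sw$c1 <- fr$c2; sw$c2 <- fr$c1
    if (is.finite(v)) expect_equal(d_f(sw), -v, tolerance = 1e-12)
    if (is.finite(D)) expect_equal(patterson_d(sw), -D, tolerance = 1e-12)
  }
})

test_that("BBAA sites enter d_f's denominator but not its numerator", {
  base <- freqs_table(p1 = c(0, 1), p2 = c(1, 0), p3 = 1)
  with_bbaa <- rbind(base, freqs_table(1, 1, 0))
  tm0 <- distfrac:::site_terms(base)
  tm1 <- distfrac:::site_terms(with_bbaa)
  expect_equal(sum(tm1$num), sum(tm0$num))
  expect_gt(sum(tm1$den_df), sum(tm0$den_df))
})

test_that("Laplace smoothing rebuilds distances from smoothed p1/p2 only", {
  fr <- freqs_table(p1 = 0, p2 = 0, p3 = 1)   # d_f undefined unsmoothed
  expect_true(is.nan(d_f(fr)))
  sm <- d_f(fr, laplace = TRUE)
  p1s <- laplace_smooth(0, 8); p2s <- laplace_smooth(0, 8)
  num <- p2s * site_dxy(p1s, 1) - p1s * site_dxy(p2s, 1)
  den <- p2s * site_dxy(p1s, 1) + p1s * site_dxy(p2s, 1)
  expect_equal(sm, num / den)
  # p3 is never smoothed
  fr2 <- freqs_table(0, 1, 1)
  tm <- distfrac:::site_terms(fr2, laplace = TRUE)
  expect_equal(tm$den_D, 1 * site_dxy(0.1, 0.9))
})
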