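test_that("sim_config validates the demography", {
  expect_error(sim_config(f = 1.2), "f must be")
  expect_error(sim_config(t_gf = 1.5), "t_gf")
  expect_error(sim_config(t12 = 2, t123 = 1), "t12 <= t123")
  expect_s3_class(sim_config(t12 = 1, t123 = 1), "sim_config")  # trident history
  expect_error(sim_config(samples_per_pop = 1), "samples_per_pop")
})

test_that("simulation is reproducible given a seed", {
  cfg <- sim_config(f = 0.4, L = 1000, rho = 10, model = "infinite_sites")
  set.seed(77); a <- simulate_locus(cfg)
  set.seed(77); b <- simulate_locus(cfg)
  expect_identical(a$alleles, b$alleles)
  expect_identical(a$positions, b$positions)
  g1 <- simulate_grid(cfg, f_values = c(0, 1), reps = 3, seed = 5)
  g2 <- simulate_grid(cfg, f_values = c(0, 1), reps = 3, seed = 5)
  expect_identical(g1, g2)
})

test_that("hky_transition is a proper reversible transition kernel", {
  P <- hky_transition(0.2, kappa = 3, base_freq = c(0.3, 0.2, 0.2, 0.3))
  expect_equal(rowSums(P), rep(1, 4))
  expect_true(all(P >= 0))
  # detailed balance
  pi4 <- c(0.3, 0.2, 0.2, 0.3)
  expect_equal(diag(pi4) %*% P, t(diag(pi4) %*% P), tolerance = 1e-12)
  # tau -> 0 identity; tau -> infinity equilibrium
  expect_equal(hky_transition(0), diag(4), tolerance = 1e-8)
  Pinf <- hky_transition(500, kappa = 3, base_freq = pi4)
  expect_equal(Pinf, matrix(pi4, 4, 4, byrow = TRUE), tolerance = 1e-8)
  # transitions exceed transversions at short times
  expect_gt(P[1, 3], P[1, 2])
})

test_that("expected segregating sites scale with locus length and match theory", {
  # near-panmictic limit: all splits at ~0, n = 32 haplotypes, E[S] = s L H_{n-1}
  cfg <- sim_config(f = 0, t12 = 1e-9, t123 = 2e-9, t123O = 3e-9, t_gf = 1e-10,
                    rho = 0, L = 5000, model = "infinite_sites")
  set.seed(21)
  S <- replicate(60, nrow(simulate_locus(cfg)$alleles))
  theory <- 0.01 * 5000 * sum(1 / seq_len(31))
  expect_lt(abs(mean(S) - theory), 3 * stats::sd(S) / sqrt(length(S)))
  # linear growth in L
  cfg2 <- cfg; cfg2$L <- 10000L
  S2 <- replicate(60, nrow(simulate_locus(cfg2)$alleles))
  expect_lt(abs(mean(S2) / mean(S) - 2), 0.25)
})

test_that("without introgression D is centred at zero", {
  cfg <- sim_config(f = 0, model = "infinite_sites")
  g <- simulate_grid(cfg, f_values = 0, reps = 500, seed = 42)
  D <- g$D[is.finite(g$D)]
  expect_lt(abs(mean(D)), 3 * stats::sd(D) / sqrt(length(D)))
  # d_f is tightly centred too
  expect_lt(abs(mean(g$d_f)), 0.02)
})

test_that("full replacement drives d_f and f_d towards one", {
  cfg <- sim_config(f = 1, t_gf = 0.01, model = "infinite_sites")
  g <- simulate_grid(cfg, f_values = 1, reps = 30, seed = 43)
  expect_gt(mean(g$d_f), 0.95)
  expect_gt(mean(g$f_d), 0.75)   # bounded below 1 by drift since the pulse
  expect_gt(mean(g$D), 0.95)
})

test_that("the admixture pulse erodes the donor-recipient distance only", {
  # P3->P2 gene flow: d23 shrinks with f, d13 untouched
  cfg <- sim_config(direction = "P3->P2", model = "infinite_sites")
  g <- simulate_grid(cfg, f_values = c(0, 0.8), reps = 60, seed = 44)
  m0 <- colMeans(g[g$f == 0, c("d13", "d23")])
  m8 <- colMeans(g[g$f == 0.8, c("d13", "d23")])
  expect_lt(m8[["d23"]], 0.8 * m0[["d23"]])
  expect_lt(abs(m8[["d13"]] - m0[["d13"]]) / m0[["d13"]], 0.1)
  # symmetric background: d13 = d23 at f = 0
  expect_lt(abs(m0[["d13"]] - m0[["d23"]]) / m0[["d13"]], 0.1)
})

test_that("P3->P1 gene flow drives d_f negative", {
  cfg <- sim_config(f = 0.8, direction = "P3->P1", model = "infinite_sites")
  g <- simulate_grid(cfg, f_values = 0.8, reps = 25, seed = 45)
  expect_lt(mean(g$d_f), -0.5)
  expect_lt(mean(g$D), -0.5)
})

test_that("detection sets are labelled and sized correctly", {
  cfg <- sim_config(f = 0.5, L = 500, rho = 5, model = "infinite_sites")
  set <- simulate_detection_set(cfg, cfg, 10, 10, seed = 9)
  expect_equal(nrow(set), 20)
  expect_equal(sum(set$introgressed), 10)
  expect_true(mean(set$d_f[set$introgressed], na.rm = TRUE) >
              mean(set$d_f[!set$introgressed], na.rm = TRUE))
})

test_that("hky and infinite-sites models agree on coarse statistics", {
  cfg_h <- sim_config(f = 0.5, L = 2000)
  cfg_i <- cfg_h; cfg_i$model <- "infinite_sites"
  gh <- simulate_grid(cfg_h, f_values = 0.5, reps = 40, seed = 71)
  gi <- simulate_grid(cfg_i, f_values = 0.5, reps = 40, seed = 72)
  # the HKY + strict-polarization pipeline retains fewer sites (multiple
  # hits, multiallelic columns, outgroup-polymorphic sites dropped) but the
  # same order of density
  ratio <- mean(gh$n_snps) / mean(gi$n_snps)
  expect_lt(ratio, 1)
  expect_gt(ratio, 0.55)
  se <- sqrt(stats::var(gh$d_f) / 40 + stats::var(gi$d_f) / 40)
  expect_lt(abs(mean(gh$d_f) - mean(gi$d_f)), 4 * se)
})

test_that("simulate_chromosome concatenates loci with shifted coordinates", {
  cfg <- sim_config(f = 0, L = 1000, rho = 5, model = "infinite_sites")
  hm <- simulate_chromosome(cfg, n_loci = 5, tract = c(2000, 3000),
                            tract_f = 1, seed = 3)
  expect_true(all(diff(hm$positions) > 0))
  expect_lt(max(hm$positions), 5000)
  sc <- window_scan(hm, 1000, 1000, smooth = FALSE)
  expect_equal(nrow(sc), 5)
  expect_equal(which.max(sc$d_f), 3)
})
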