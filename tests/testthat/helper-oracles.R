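# Independent brute-force oracles used across tests.

# Mean pairwise mismatch between two populations of haplotypes (0/1
# vectors), counting all nx * ny pairs.
brute_dxy <- function(hx, hy) {
  mean(outer(hx, hy, FUN = "!="))
}

# Literal ABBA/BABA pattern counting for windows where every population is
# fixed at every site.  `pat` is a matrix sites x 4 of 0/1 fixed states
# (P1, P2, P3, O).
pattern_count_D <- function(pat) {
  abba <- sum(pat[, 1] == 0 & pat[, 2] == 1 & pat[, 3] == 1 & pat[, 4] == 0)
  baba <- sum(pat[, 1] == 1 & pat[, 2] == 0 & pat[, 3] == 1 & pat[, 4] == 0)
  if (abba + baba == 0) NaN else (abba - baba) / (abba + baba)
}

# Site-frequency table for a matrix of fixed four-population states.
freqs_from_patterns <- function(pat, n = 8L) {
  data.frame(position = seq_len(nrow(pat)) - 1,
             p1 = pat[, 1], p2 = pat[, 2], p3 = pat[, 3], p4 = pat[, 4],
             n1 = n, n2 = n, n3 = n, n4 = n,
             c1 = as.integer(pat[, 1] * n), c2 = as.integer(pat[, 2] * n),
             c3 = as.integer(pat[, 3] * n), c4 = as.integer(pat[, 4] * n))
}

# Frequency table from explicit per-population frequencies.
freqs_table <- function(p1, p2, p3, p4 = 0, n = 8L) {
  k <- max(length(p1), length(p2), length(p3), length(p4))
  p1 <- rep_len(p1, k); p2 <- rep_len(p2, k)
  p3 <- rep_len(p3, k); p4 <- rep_len(p4, k)
  data.frame(position = seq_len(k) - 1, p1 = p1, p2 = p2, p3 = p3, p4 = p4,
             n1 = n, n2 = n, n3 = n, n4 = n,
             c1 = as.integer(round(p1 * n)), c2 = as.integer(round(p2 * n)),
             c3 = as.integer(round(p3 * n)), c4 = as.integer(round(p4 * n)))
}

# All 16 fixed four-taxon site patterns.
all_fixed_patterns <- function() {
  as.matrix(expand.grid(p1 = 0:1, p2 = 0:1, p3 = 0:1, p4 = 0:1))
}

# Naive hand implementation of the BH step-up rule.
stepup_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# A small deterministic hap_matrix used by io/scan tests.
toy_hap_matrix <- function() {
  # sites: ABBA, BABA, BBAA, monomorphic-derived P3 only
  G <- rbind(c(rep(0L, 2), rep(1L, 2), rep(1L, 2), rep(0L, 2)),
             c(rep(1L, 2), rep(0L, 2), rep(1L, 2), rep(0L, 2)),
             c(rep(1L, 2), rep(1L, 2), rep(0L, 2), rep(0L, 2)),
             c(rep(0L, 2), rep(0L, 2), rep(1L, 2), rep(0L, 2)))
  hap_matrix(G, c(10, 20, 30, 40), rep(c("P1", "P2", "P3", "O"), each = 2),
             polarized = TRUE, source = "toy")
}
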