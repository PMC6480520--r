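#' Polarize sites by the outgroup and build the site-frequency table
#'
#' The outgroup O defines the ancestral state.  Under the `"strict"` policy
#' only sites where the outgroup is fixed for one allele are kept; that
#' allele becomes ancestral (coded 0) and the site-frequency table then has
#' p4 = 0 at every retained site.  Under `"major"` the outgroup's major
#' allele is called ancestral and nothing is dropped, except sites where
#' the outgroup is at exactly 50/50, for which no defensible ancestral call
#' exists.
#'
#' @param x a [hap_matrix()].
#' @param policy `"strict"` (default) or `"major"`.
#' @return The polarized `hap_matrix`, with updated dropped-site counters.
#' @export
polarize <- function(x, policy = c("strict", "major")) {
  policy <- match.arg(policy)
  stopifnot(inherits(x, "hap_matrix"))
  oc <- pop_cols(x, "O")
  if (!length(oc)) stop("outgroup population O is empty")
  G <- x$alleles
  if (nrow(G) == 0) {
    x$polarized <- TRUE
    return(x)
  }
  og <- G[, oc, drop = FALSE]
  n1 <- rowSums(og == 1L, na.rm = TRUE)
  nc <- rowSums(!is.na(og))
  frq <- ifelse(nc > 0, n1 / nc, NA_real_)
  if (policy == "strict") {
    keep <- !is.na(frq) & (frq == 0 | frq == 1)
    flip <- frq == 1
  } else {
    keep <- !is.na(frq) & frq != 0.5
    flip <- frq > 0.5
  }
  n_drop <- sum(!keep)
  flip <- flip[keep]
  G <- G[keep, , drop = FALSE]
  if (any(flip)) G[flip, ] <- 1L - G[flip, , drop = FALSE]
  x$alleles <- G
  x$positions <- x$positions[keep]
  x$polarized <- TRUE
  x$dropped <- add_counter(x$dropped, "outgroup_unresolved", n_drop)
  x
}

add_counter <- function(counters, name, k) {
  if (k == 0 && !name %in% names(counters)) return(counters)
  counters[name] <- (if (name %in% names(counters)) counters[[name]] else 0L) + as.integer(k)
  counters
}

#' Per-site derived-allele frequencies for the four populations
#'
#' Computes, for every biallelic site, the derived-allele frequency and the
#' number of successfully called haplotypes in each of P1, P2, P3 and O.
#' Frequencies are computed over non-missing haplotypes; sites where any
#' population has zero called haplotypes are dropped (with a counter
#' recorded as an attribute), as are sites that are monomorphic across all
#' four populations.
#'
#' @param x a polarized [hap_matrix()].
#' @param drop_monomorphic drop sites with no variation across all
#'   populations (default `TRUE`; they contribute nothing to any statistic).
#' @return data.frame with columns `position`, `p1`..`p4`, `n1`..`n4`,
#'   `c1`..`c4` (derived-allele counts), one row per retained site.
#' @export
site_frequencies <- function(x, drop_monomorphic = TRUE) {
  stopifnot(inherits(x, "hap_matrix"))
  if (!x$polarized)
    warning("hap_matrix is not polarized; allele 1 may not be the derived allele")
  G <- x$alleles
  out <- data.frame(position = x$positions)
  labs <- c("P1", "P2", "P3", "O")
  for (i in seq_along(labs)) {
    cols <- pop_cols(x, labs[i])
    sub <- G[, cols, drop = FALSE]
    cc <- rowSums(sub == 1L, na.rm = TRUE)
    nn <- rowSums(!is.na(sub))
    out[[paste0("c", i)]] <- as.integer(cc)
    out[[paste0("n", i)]] <- as.integer(nn)
    out[[paste0("p", i)]] <- ifelse(nn > 0, cc / nn, NA_real_)
  }
  ord <- c("position", paste0("p", 1:4), paste0("n", 1:4), paste0("c", 1:4))
  out <- out[, ord]
  called <- out$n1 > 0 & out$n2 > 0 & out$n3 > 0 & out$n4 > 0
  n_uncalled <- sum(!called)
  out <- out[called, , drop = FALSE]
  n_mono <- 0L
  if (drop_monomorphic && nrow(out)) {
    ctot <- out$c1 + out$c2 + out$c3 + out$c4
    ntot <- out$n1 + out$n2 + out$n3 + out$n4
    mono <- ctot == 0L | ctot == ntot
    n_mono <- sum(mono)
    out <- out[!mono, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "dropped") <- c(x$dropped,
                            uncalled_population = n_uncalled,
                            monomorphic = as.integer(n_mono))
  out
}
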