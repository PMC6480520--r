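#' Read ms-style segregating-sites output
#'
#' Parses the classic Hudson ms text dialect: replicate blocks introduced
#' by `//` (or, for pre-stripped streams, detected at each `segsites:`
#' line), a `positions:` line with coordinates in `[0, 1]`, and one 0/1
#' haplotype string per sample row.  The 0/1 coding is taken as
#' ancestral/derived directly, since ms simulates relative to the
#' ancestral state; positions are scaled to `[0, L)` bp.
#'
#' @param path path to an ms output file (or a character vector of lines).
#' @param samples_per_pop haplotypes per population, in the block order
#'   P1, P2, P3, O (the ms `-I 4 n n n n` layout).
#' @param L locus length in bp used to scale positions.
#' @return list of [hap_matrix()] objects, one per replicate.
#' @export
read_ms <- function(path, samples_per_pop, L = 1) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  ntot <- sum(samples_per_pop)
  pops <- block_pops(samples_per_pop)
  seg_at <- grep("^segsites:", lines)
  if (!length(seg_at)) return(list())
  reps <- vector("list", length(seg_at))
  for (r in seq_along(seg_at)) {
    i <- seg_at[r]
    S <- as.integer(sub("^segsites:\\s*", "", lines[i]))
    if (S == 0) {
      reps[[r]] <- hap_matrix(matrix(integer(), 0, ntot), numeric(),
                              pops, polarized = TRUE, source = "ms")
      next
    }
    stopifnot(grepl("^positions:", lines[i + 1]))
    pos <- as.numeric(strsplit(sub("^positions:\\s*", "", lines[i + 1]),
                               "\\s+")[[1]])
    if (length(pos) != S) stop("positions line length does not match segsites")
    rows <- lines[(i + 2):(i + 1 + ntot)]
    if (length(rows) != ntot || any(nchar(rows) != S))
      stop("haplotype row count or width does not match segsites/sample size")
    G <- matrix(vapply(rows, function(z) as.integer(strsplit(z, "")[[1]]),
                       integer(S), USE.NAMES = FALSE), nrow = S)
    # ms can emit duplicate positions at low precision; keep first
    posL <- pos * L
    keep <- !duplicated(posL)
    reps[[r]] <- hap_matrix(G[keep, , drop = FALSE], posL[keep], pops,
                            polarized = TRUE, source = "ms",
                            dropped = c(duplicate_position = sum(!keep)))
  }
  reps
}

#' Write haplotype matrices in the ms dialect
#'
#' Inverse of [read_ms()]: writes a two-line pseudo-header followed by one
#' `//` block per replicate.  Positions are rescaled to `[0, 1]` by `L`.
#'
#' @param x a [hap_matrix()] or list of them.
#' @param path output file.
#' @param L locus length in bp used to rescale positions.
#' @return `path`, invisibly.
#' @export
write_ms <- function(x, path, L = 1) {
  if (inherits(x, "hap_matrix")) x <- list(x)
  ntot <- ncol(x[[1]]$alleles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ms %d %d", ntot, length(x)), "0 0 0"), con)
  for (hm in x) {
    writeLines("", con)
    writeLines("//", con)
    S <- nrow(hm$alleles)
    writeLines(sprintf("segsites: %d", S), con)
    if (S > 0) {
      writeLines(paste("positions:",
                       paste(sprintf("%.10f", hm$positions / L),
                             collapse = " ")), con)
      writeLines(apply(hm$alleles, 2, paste, collapse = ""), con)
    }
  }
  invisible(path)
}
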