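#' Read a multiple-sequence alignment and extract variant sites
#'
#' Accepts FASTA or (relaxed/sequential) PHYLIP, the format written by
#' seq-gen.  Variant columns are extracted case-insensitively; gaps, `N`
#' and `?` are treated as missing; columns with more than two bases among
#' called sequences are dropped with a counter.  The resulting
#' [hap_matrix()] is unpolarized (allele 0 is the alphabetically first
#' observed base); use [polarize()] to orient alleles by the outgroup.
#'
#' @param path alignment file.
#' @param format `"auto"` (default; sniffs a leading `>`), `"fasta"` or
#'   `"phylip"`.
#' @param popmap named character vector sample -> population; when `NULL`,
#'   `samples_per_pop` assigns populations in contiguous blocks
#'   (P1, P2, P3, O), the layout of the simulation pipeline.
#' @param samples_per_pop block sizes used when `popmap` is `NULL`.
#' @return an unpolarized [hap_matrix()] with 0-based column positions.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "phylip"),
                           popmap = NULL, samples_per_pop = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1)
    format <- if (startsWith(trimws(first), ">")) "fasta" else "phylip"
  }
  if (format == "fasta") {
    dna <- ape::read.dna(path, format = "fasta", as.character = TRUE,
                         as.matrix = TRUE)
  } else {
    dna <- tryCatch(
      ape::read.dna(path, format = "sequential", as.character = TRUE,
                    as.matrix = TRUE),
      error = function(e)
        ape::read.dna(path, format = "interleaved", as.character = TRUE,
                      as.matrix = TRUE))
  }
  if (is.null(dim(dna))) stop("ragged or empty alignment")
  aln <- toupper(dna)
  aln[aln %in% c("-", "N", "?", ".")] <- NA
  nseq <- nrow(aln)
  if (!is.null(popmap)) {
    nm <- rownames(aln)
    missing <- setdiff(names(popmap), nm)
    if (length(missing))
      stop("samples in population map absent from alignment: ",
           paste(missing, collapse = ", "))
    aln <- aln[names(popmap), , drop = FALSE]
    pops <- unname(popmap)
  } else {
    if (is.null(samples_per_pop))
      stop("provide either popmap or samples_per_pop")
    if (sum(samples_per_pop) != nseq)
      stop("sum(samples_per_pop) does not match the number of sequences")
    pops <- block_pops(samples_per_pop)
  }
  S <- ncol(aln)
  alleles <- vector("list", S)
  keep <- logical(S)
  n_multi <- 0L
  for (s in seq_len(S)) {
    col <- aln[, s]
    obs <- sort(unique(col[!is.na(col)]))
    if (length(obs) < 2) next
    if (length(obs) > 2) { n_multi <- n_multi + 1L; next }
    keep[s] <- TRUE
    alleles[[s]] <- as.integer(col == obs[2])  # NA stays NA
  }
  G <- if (any(keep)) do.call(rbind, alleles[keep]) else
    matrix(integer(), 0, nseq)
  hap_matrix(G, which(keep) - 1, pops, polarized = FALSE,
             source = paste0("alignment/", format),
             dropped = c(multiallelic = n_multi))
}

#' Write an alignment in sequential PHYLIP (relaxed names)
#'
#' @param alignment character matrix, sequences x sites (e.g. from
#'   `simulate_locus(..., return_alignment = TRUE)`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(alignment, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(" %d %d", nrow(alignment), ncol(alignment)), con)
  nm <- rownames(alignment)
  if (is.null(nm)) nm <- sprintf("s%02d", seq_len(nrow(alignment)))
  writeLines(paste(format(nm, width = max(10, nchar(nm) + 1)),
                   apply(alignment, 1, paste, collapse = "")), con)
  invisible(path)
}
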