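#' Haplotype matrix for four-taxon analyses
#'
#' A `hap_matrix` holds biallelic sites as rows and haplotypes as columns,
#' with alleles coded 0/1 (`NA` for missing calls).  After polarization
#' (see [polarize()]) allele 1 is the derived allele as defined by the
#' outgroup.  Each haplotype belongs to one of the populations `P1`, `P2`,
#' `P3` (the candidate donor) or `O` (the outgroup) on the species tree
#' (((P1,P2),P3),O).
#'
#' @param alleles integer matrix, sites x haplotypes, entries 0/1/`NA`.
#' @param positions numeric vector of strictly increasing site coordinates
#'   (0-based bp; may be fractional for continuous-position simulations).
#' @param pops character vector, one of `"P1"`, `"P2"`, `"P3"`, `"O"` per
#'   haplotype column.
#' @param polarized logical; `TRUE` when allele 1 is known to be derived.
#' @param source short tag describing where the data came from.
#' @param dropped named integer vector of dropped-site counters carried
#'   along from readers/filters.
#' @return An object of class `hap_matrix`.
#' @export
hap_matrix <- function(alleles, positions, pops, polarized = FALSE,
                       source = "unknown", dropped = integer()) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  positions <- as.numeric(positions)
  pops <- as.character(pops)
  if (nrow(alleles) != length(positions))
    stop("number of rows of `alleles` must equal length(positions)")
  if (ncol(alleles) != length(pops))
    stop("number of columns of `alleles` must equal length(pops)")
  if (!all(pops %in% c("P1", "P2", "P3", "O")))
    stop("population labels must be drawn from {P1, P2, P3, O}")
  if (nrow(alleles) > 0 && any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  bad <- alleles[!is.na(alleles)]
  if (length(bad) && !all(bad %in% c(0L, 1L)))
    stop("alleles must be coded 0/1 or NA")
  structure(
    list(alleles = alleles, positions = positions, pops = pops,
         polarized = isTRUE(polarized), source = source,
         dropped = dropped),
    class = "hap_matrix")
}

#' @export
print.hap_matrix <- function(x, ...) {
  tab <- table(factor(x$pops, levels = c("P1", "P2", "P3", "O")))
  cat(sprintf("hap_matrix: %d sites x %d haplotypes [%s]%s\n",
              nrow(x$alleles), ncol(x$alleles), x$source,
              if (x$polarized) " (polarized)" else ""))
  cat("  haplotypes: ", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  if (length(x$dropped))
    cat("  dropped sites: ",
        paste(names(x$dropped), x$dropped, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.hap_matrix <- function(x) dim(x$alleles)

n_snps <- function(x) nrow(x$alleles)

pop_cols <- function(x, pop) which(x$pops == pop)

#' Read a two-column population map
#'
#' The file format is whitespace- or tab-separated with two columns:
#' sample name and population label (`P1`, `P2`, `P3` or `O`).  Lines
#' starting with `#` are ignored.
#'
#' @param path path to the population map file.
#' @return named character vector mapping sample name to population label.
#' @export
read_popmap <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("sample", "pop"),
                           colClasses = "character")
  if (anyDuplicated(tab$sample))
    stop("duplicated sample names in population map")
  bad <- setdiff(unique(tab$pop), c("P1", "P2", "P3", "O"))
  if (length(bad))
    stop("invalid population labels in population map: ",
         paste(bad, collapse = ", "))
  stats::setNames(tab$pop, tab$sample)
}

# Population labels assigned in contiguous blocks, the layout produced by
# ms-style simulators (`-I 4 n n n n`): first block P1, then P2, P3, O.
block_pops <- function(samples_per_pop) {
  if (length(samples_per_pop) != 4)
    stop("samples_per_pop must have length 4 (P1, P2, P3, O)")
  rep(c("P1", "P2", "P3", "O"), times = samples_per_pop)
}
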