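#' Read haplotypes from a VCF
#'
#' Biallelic SNPs only (multi-allelic and indel records are dropped with
#' counters).  Phased diploid genotypes (`0|1`) contribute two haplotypes;
#' haploid calls (`0`, `1`) contribute one.  Unphased heterozygotes are
#' handled per `het_policy`: `"drop"` removes the site, `"random"`
#' assigns the two alleles to the two haplotypes in random order (seed the
#' RNG for reproducibility), `"error"` aborts.  Coordinates are converted
#' to 0-based.
#'
#' @param path path to a VCF (plain or bgzipped).
#' @param popmap named character vector from [read_popmap()]; every mapped
#'   sample must be present in the VCF header.
#' @param het_policy `"drop"`, `"random"` or `"error"`.
#' @return an unpolarized [hap_matrix()]; follow with [polarize()].
#' @export
read_vcf <- function(path, popmap, het_policy = c("drop", "random", "error")) {
  het_policy <- match.arg(het_policy)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  missing <- setdiff(names(popmap), samples)
  if (length(missing))
    stop("samples in population map absent from VCF: ",
         paste(missing, collapse = ", "))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n_rec <- nrow(fix)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp <- !is.na(ref) & !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_notsnp <- sum(!snp)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = n_rec)
  gt <- gt[snp, names(popmap), drop = FALSE]
  pos <- as.numeric(fix[snp, "POS"]) - 1
  # per-sample haplotype expansion
  cols <- list(); pops <- character()
  n_het_dropped <- 0L
  site_ok <- rep(TRUE, nrow(gt))
  for (sm in names(popmap)) {
    g <- gt[, sm]
    g[is.na(g)] <- "."
    ploidy2 <- grepl("[|/]", g[g != "."])
    two <- length(ploidy2) > 0 && any(ploidy2)
    a1 <- a2 <- rep(NA_integer_, length(g))
    tok <- strsplit(g, "[|/]")
    first <- vapply(tok, function(z) z[1], "")
    second <- vapply(tok, function(z) if (length(z) > 1) z[2] else NA_character_, "")
    a1[first == "0"] <- 0L; a1[first == "1"] <- 1L
    a2[second == "0"] <- 0L; a2[second == "1"] <- 1L
    unphased_het <- grepl("/", g) & !is.na(a1) & !is.na(a2) & a1 != a2
    if (any(unphased_het)) {
      if (het_policy == "error")
        stop("unphased heterozygote for sample ", sm,
             " (set het_policy to 'drop' or 'random')")
      if (het_policy == "drop") {
        site_ok[unphased_het] <- FALSE
      } else {
        swap <- unphased_het & (stats::runif(length(g)) < 0.5)
        tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
      }
    }
    if (two) {
      cols <- c(cols, list(a1, a2))
      pops <- c(pops, popmap[[sm]], popmap[[sm]])
    } else {
      cols <- c(cols, list(a1))
      pops <- c(pops, popmap[[sm]])
    }
  }
  if (het_policy == "drop") n_het_dropped <- sum(!site_ok)
  G <- do.call(cbind, cols)
  G <- G[site_ok, , drop = FALSE]
  pos <- pos[site_ok]
  ord <- order(pos)
  G <- G[ord, , drop = FALSE]; pos <- pos[ord]
  dup <- duplicated(pos)
  hap_matrix(G[!dup, , drop = FALSE], pos[!dup], pops, polarized = FALSE,
             source = "vcf",
             dropped = c(not_biallelic_snp = n_notsnp,
                         unphased_het = n_het_dropped,
                         duplicate_position = sum(dup)))
}
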