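Package: distfrac
Title: Distance-Based Four-Taxon Introgression Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection and quantification of introgression on a four-taxon
    tree (((P1,P2),P3),O) through the distance fraction d_f and its
    companions Patterson's D, f_hom and f_d, all expressed through pairwise
    nucleotide diversity. Includes readers for VCF, sequence alignments and
    ms-style haplotype data; a structured-coalescent simulator with
    recombination, an admixture pulse and HKY or infinite-sites mutations;
    sliding-window genome scans with weighted block-jackknife Z-values and
    Benjamini-Hochberg FDR control; and an evaluation harness scoring
    estimator accuracy (adjusted R-squared, lack-of-fit and pure-error sums
    of squares) and detection power (ROC AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    pROC,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
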