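Package: reodeg
Title: Differential Expression from Within-Sample Relative Expression Orderings
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects genes whose absolute mRNA abundance changes between two
    phenotypes by comparing within-sample relative expression orderings (REOs)
    of gene pairs, rather than normalized expression magnitudes.  Gene pairs
    with significantly stable orderings are identified in each phenotype with
    an exact binomial test and Benjamini-Hochberg correction; per-gene
    contingency tables of consistent versus reversed orderings are then
    scored with Fisher's exact test, iteratively excluding candidate
    differentially expressed genes as ranking partners until the candidate
    count stabilises.  Includes a negative-binomial cohort simulator with
    spike-in fold changes and transcriptome-size rescaling, confusion-matrix
    and reproducibility (POG/concordance) metrics, hypergeometric gene-set
    enrichment, and an experiment workbench with an optional count-based
    comparator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    limma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    edgeR,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
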