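Package: sharedfolds
Title: Structural Fold-Space Overlap Testing for Protein Domain Classes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether a functional class of protein domains (such as
    viral capsid proteins) is segregated in structural fold space. Provides a
    TM-score based structural aligner for CA traces, (1 - TM-score)
    structural distances, sequence-identity redundancy filtering,
    average-linkage clustering of the focus set with medoid extraction under
    a maximum intra-cluster distance criterion, the "shared folds" overlap
    statistic (distinct SCOP folds among non-focus domains within a distance
    cutoff of the focus set), and a permutation-test null with self-fold
    exclusion yielding one-tailed empirical p-values. Includes synthetic
    generators for latent fold-family distance matrices and ideal-geometry
    CA-trace structure sets, plus an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
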