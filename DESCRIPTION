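Package: lppf
Title: Linear Perfect Phylogeny Flipping for Single-Cell Tumor Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Classifies a tumor's evolutionary trajectory as linear or
    branched from single-cell DNA sequencing data. Given a binary
    cells-by-mutations genotype matrix, an exact branch-and-bound solver
    finds the minimum number of 0-to-1 flips (putative false negatives)
    that turn the matrix into a linear perfect phylogeny, subject to a cap
    on 1-to-0 flips (false positives). The implied false-negative fraction
    is then compared between a linear and a branched hypothesis using a
    beta-binomial Bayes factor, or against a hard threshold. Includes a
    clone-tree simulator with false-negative, false-positive and doublet
    error injection, ancestor-descendant tree distance, read-count
    discretization, and SCITE-compatible matrix input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    igraph,
    withr,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
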