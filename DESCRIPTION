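Package: sgascreen
Title: Colony-Fitness Analysis of Synthetic Genetic Array Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of quadruplicate 1536-format synthetic genetic array
    (SGA) colony screens comparing several query alleles of one gene against
    a neutral control. Provides plate-level normalization (plate, row/column
    and spatial-surface correction), failed-mutant and genetic-linkage
    filtering, moderated weighted mixed linear models with a shared
    technical-replicate correlation and empirical-Bayes variance shrinkage,
    significant-interaction calling with Benjamini-Hochberg control, a
    comparative classification that separates an allele's interaction
    signature into shared, residual/restored, increased-sensitivity and
    unique gain-of-function categories, hypergeometric gene-set
    over-representation, disease-slim mapping, and a fully specified
    synthetic-screen generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo: Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    limma,
    yaml,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    optparse
Config/testthat/edition: 3
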