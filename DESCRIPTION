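Package: riboTE
Title: Integrated RNA-Seq and Ribo-Seq Analysis of Translational Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential expression and translation-efficiency analysis for
    paired RNA-Seq and ribosome-profiling count data from bacteria grown under
    two conditions. Implements median-of-ratios normalization, method-of-moments
    negative-binomial dispersion estimation with trend shrinkage, Wald tests for
    condition effects and condition-by-assay (translation efficiency)
    interactions, translational-buffering correlation, operon subunit
    stoichiometry from ribosome-protected-fragment levels, minimum-free-energy
    folding of 5'UTRs under a nearest-neighbor stacking model, length-normalized
    metagene footprint-coverage profiles, and hypergeometric term enrichment
    with kappa-score grouping. A synthetic-data generator reproduces the
    statistical structure of such experiments so every stage is testable
    without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    Rcpp,
    Biostrings,
    igraph,
    yaml,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    BiocGenerics,
    DESeq2,
    rtracklayer,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
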