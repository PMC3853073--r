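Package: mvrforest
Title: Multivariate Random-Forest Regression for Genome-Wide Association
    Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Random-forest regression for genome-wide association studies
    with multivariate quantitative traits.  Trees are grown on additive
    0/1/2 genotype codings with either a covariance-weighted sum-of-squares
    node-splitting criterion or its distance-based equivalent, which
    evaluates node heterogeneity through pairwise squared phenotype
    distances and whose cost does not grow with the number of traits.
    The forest is orchestrated through an in-process map/shuffle/reduce
    contract that makes results independent of how trees are batched over
    workers, and aggregates three keyed emission streams into out-of-bag
    prediction error, information-gain SNP importance, and an
    inter-sample proximity matrix.  Downstream tools cover SNP ranking and
    its stability, SNP-to-gene mapping with a gene-rank permutation test
    under false-discovery-rate control, classical multidimensional scaling
    of genetic and phenotypic distances, Mantel tests, severity scoring
    along a cluster-to-cluster axis, mutated-state counts and mutation-
    pattern mining, plus a calibrated genotype/phenotype simulator, VCF and
    TSV readers, and SNP quality-control filters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    readr,
    ggplot2,
    generics,
    vegan,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
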