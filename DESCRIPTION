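Package: epitensor
Title: Tensor Completion for Imputing Missing Epigenomic Signal Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Imputes missing epigenomic experiments (cell type x assay x
    genomic position) by completing a third-order signal tensor with a
    PARAFAC/CANDECOMP factorization augmented with per-dimension bias
    vectors. Provides the full training procedure (seeded initialization,
    burn-in, partition-parallel stochastic gradient descent with
    element-wise parameter averaging, Adam with Nesterov momentum and
    decay schedules, rank-sum convergence detection, restart line search,
    and a closed-form ridge solve of the genome parameters), an additive
    main-effects baseline, ten imputation quality measures with
    cross-method comparison statistics, bedGraph/BED input handling with
    25 bp binning and an inverse hyperbolic sine transform, stratified
    train/validation/test splitting of the experiment grid, and a seeded
    synthetic low-rank tensor generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
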