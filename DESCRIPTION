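Package: trscore
Title: Transcriptomic Risk Scores from Multi-Tissue TWAS Summary Statistics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds per-individual transcriptomic risk scores (TRS) by
    weighting standardized observed gene expression with signed gene-level
    Z-scores from transcriptome-wide association studies (TWAS), tests
    their association with a binary phenotype using covariate-adjusted
    logistic regression with a permutation null over a p-value threshold
    scan, converts likelihood-based pseudo-R2 to the liability scale for
    ascertained case-control samples, estimates the effective number of
    correlated tests (Galwey) with the derived Sidak threshold, supports
    locus-pruned and colocalization-restricted score variants, and
    compares and combines the TRS with a polygenic risk score. Includes a
    synthetic-data generator that emulates all required inputs with
    controllable signal structure so the full pipeline is testable
    without access to clinical cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    lmtest,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'data-io.R'
    'simulate.R'
    'trs.R'
    'association.R'
    'multiplicity.R'
    'trscore-package.R'
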