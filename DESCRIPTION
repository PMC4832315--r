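Package: mrcombine
Title: Combining Multiple Genetic Instruments in Mendelian Randomization
    with Summarized Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimators for Mendelian randomization analyses that combine
    several genetic instrumental variables into a single causal estimate
    from summarized (per-variant) association data: the summarized-data
    allele score estimator with a delta-method standard error, the
    inverse-variance weighted (IVW) summary-statistic estimator in both
    meta-analysis and weighted-regression forms, correlation-aware
    extensions for variants in linkage disequilibrium (weighted
    generalized least squares), and a bivariate-normal likelihood model
    fitted by maximum likelihood.  Individual-level reference estimators
    (OLS, two-stage least squares, allele scores), instrument-strength and
    pleiotropy diagnostics, and a simulation framework for studying weak
    instrument bias, coverage and power under different weighting schemes
    are included, together with a small command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
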