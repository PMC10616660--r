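Package: mrsummary
Title: Mendelian Randomization with Summarized Genetic Association Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimators and diagnostics for Mendelian randomization using
    summarized genetic association data (per-variant beta coefficients and
    standard errors). Implements inverse-variance weighted estimation for
    uncorrelated and correlated variants, first-stage and conditional F
    statistics for instrument strength, weak-instrument-robust debiased and
    penalized IVW estimators, continuously-updating GMM and principal-component
    GMM for densely correlated variants from a single gene region, and
    constrained maximum likelihood with selection of invalid (pleiotropic)
    instruments. Includes utilities for harmonizing signed variant correlation
    matrices to effect alleles, stochastic pruning of highly correlated
    variants, a seeded simulator of two-sample summary statistics with known
    truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
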