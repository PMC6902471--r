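Package: llct
Title: Longitudinal Linear Combination Test for Gene Set Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Self-contained gene set analysis for longitudinal phenotypes.
    A two-step procedure first summarises each subject's phenotype
    trajectories by per-subject least-squares time-trend coefficients, then
    tests whether any linear combination of a gene set's expressions is
    correlated with any linear combination of those trends, using a
    shrinkage-covariance linear combination test with subject-permutation
    p-values. Includes family-clustered permutation, a time-course mode in
    which gene expressions are the repeated outcomes, a generative
    simulation model for type-I error and power studies, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
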