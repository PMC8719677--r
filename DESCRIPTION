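Package: noisenet
Title: Condition-Dependent Gene Expression Noise and Noise Propagation
    Through Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies condition-dependent transcriptional noise from
    single-cell reporter fluorescence and attributes it to propagation of
    fluctuations through a transcription-factor regulatory network. Provides
    robust estimation of per-promoter mean and variance of log-fluorescence
    via a Gaussian-plus-uniform outlier mixture fitted by
    expectation-maximization, fitting of the condition-specific minimal
    variance envelope (noise floor) as a function of mean expression, noise
    levels defined relative to that floor, ridge-regularized inference of
    condition-dependent transcription-factor noise-propagation activities
    with posterior error bars and a permutation null, enrichment statistics
    linking noise to regulatory inputs, principal component analysis of
    gene-feature correlation structure, and a synthetic-data generator that
    emulates the measurement and network structure of genome-wide
    reporter-library flow-cytometry studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
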