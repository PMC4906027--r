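Package: esmar
Title: Multilevel AR(1) Models for Experience Sampling Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding how many levels of nesting to model in intensive
    longitudinal (experience sampling) data with multiple measurements ("beeps")
    per day and multiple days per person. Implements two-level and three-level
    autoregressive multilevel models of emotional inertia, empirical-Bayes
    centered lagged-predictor construction honoring night breaks and missing
    values, maximum-likelihood estimation of the Gaussian mixed models,
    AIC/BIC-based selection of the number of levels on a common case subset,
    simulators for the corresponding data-generating processes, and a
    Monte-Carlo harness for power and Type I error of the selection procedure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minqa,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
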