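Package: gazehgf
Title: Hierarchical Gaussian Filters and Context-Inference Networks for
    Reversal-Learning Gaze Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling anticipatory gaze in probabilistic
    reversal-learning interception tasks. Implements associative learners
    (Rescorla-Wagner, Sutton K1) and two-, three- and four-level binary
    hierarchical Gaussian filters, a coupled two-arm context-inference
    node network with autoconnection and tonic-volatility parameters,
    maximum-a-posteriori fitting with Laplace-approximate log model
    evidence, random-effects Bayesian model selection with protected
    exceedance probabilities, and parameter- and model-recovery harnesses.
    A synthetic task generator reproduces the reversal structure of the
    task (probabilistic colour-bounce contingencies, co-switching room
    cue) and simulates agent responses and gaze, and gaze preprocessing
    utilities (median/Butterworth filtering, dispersion fixation
    detection, outlier rules, dichotomization) turn raw gaze traces into
    per-trial binary responses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
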