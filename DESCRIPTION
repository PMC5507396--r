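Package: hawkesloops
Title: Loop Expansion for Spike-Train Cumulants in Nonlinear Spiking Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting and measuring spike-train statistics in
    networks of nonlinearly interacting, conditionally Poisson spiking
    neurons (nonlinear multivariate Hawkes processes). Implements
    self-consistent mean-field firing rates, the tree-level (linear
    response) propagator and second- and third-order spike-train cumulants,
    and the one-loop fluctuation corrections to firing rates, pairwise
    covariances, and linear stability. Includes an exact stochastic
    simulator with divergence detection, generators for Erdos-Renyi
    excitatory-inhibitory networks and heavy-tailed networks with
    copula-coupled power-law degrees and lognormal weights, spike-train
    cumulant estimators with block-bootstrap errors, and a config-driven
    weight-sweep experiment runner.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
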