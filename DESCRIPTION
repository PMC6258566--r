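Package: confobs
Title: Bayesian and Heuristic Observer Models of Categorization Confidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation, likelihood evaluation, Bayesian fitting and comparison of
    observer models for two-category orientation-categorization experiments with
    combined category-and-confidence reports. Implements a family of decision-boundary
    observer models (Bayesian models at three strengths with optional decision noise,
    fixed/linear/quadratic heuristic boundaries, orientation estimation, a linear
    neural readout, and a precision-weighted hybrid), trial-level lapse-mixture
    likelihoods, slice-sampling MCMC and bounded maximum-likelihood fitting,
    information criteria (AIC, BIC, AICc, WAIC), Pareto-smoothed importance-sampling
    leave-one-out cross-validation (PSIS-LOO), bootstrap aggregation of model scores
    across subjects, and model-recovery validation on synthetic data.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
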