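Package: adrsignal
Title: Sparse Bayesian Signal Detection for Adverse Drug Reactions Under
    Polypharmacy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects drug-adverse-drug-reaction (ADR) associations in
    polypharmacy cohorts with sparse Bayesian logistic regression. Provides a
    seeded synthetic-cohort generator with known sparse ground truth, a data
    curation pipeline (first-visit filtering, medication normalization,
    frequency-based drug selection, CYP450 substrate/inhibitor covariates,
    design-matrix assembly), a Polya-Gamma Gibbs sampler for logistic models
    under regularized-horseshoe and Laplace (Bayesian lasso) priors with the
    global-scale and slab-scale calibration rules for sparse problems, and
    credible-interval based classification of predictors into light/strong
    positive and negative signals with signal tables and forest plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
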