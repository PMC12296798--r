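Package: survweight
Title: Weighted Survival Regression with External Risk-Prediction Weights
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and inference for right-censored survival regression
    when each subject carries a weight derived from an external risk
    prediction model. Fits weighted Cox proportional-hazards models (Newton
    optimisation of the weighted partial likelihood, Efron or Breslow ties)
    and weighted Lin-Ying additive-hazards models (closed form), together
    with baseline cumulative-hazard estimators, model-robust sandwich
    covariances targeting the least-false parameter under misspecification,
    and perturbation (multiplier) resampling with percentile confidence
    intervals. Includes weight constructors from predicted survival
    probabilities or cumulative hazards, a synthetic data-generating module
    for proportional- and additive-hazards processes with external-cohort
    prediction emulation, and a Monte Carlo least-false-parameter oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pracma,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
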