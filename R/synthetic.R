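# Synthetic data-generating processes and the Monte Carlo least-false oracle.
#
# Event times are drawn by inverse transform from the specified conditional
# cumulative hazard; censoring is independent; covariates have compact
# support (Bernoulli, uniform, truncated normal) so the boundedness condition
# of the asymptotic theory holds by construction. For additive-hazards specs
# the constructor rejects parameter combinations that allow a negative hazard
# anywhere on the covariate support rather than clipping.

#' Specify a survival data-generating process
#'
#' @param model `"ph"` (`lambda(t|Z) = lambda0(t) exp(beta'Z)`) or `"ah"`
#'   (`lambda(t|Z) = lambda0(t) + alpha'Z`).
#' @param coef True coefficient vector (beta or alpha).
#' @param baseline Baseline hazard: `list(type = "constant", rate = )` or
#'   `list(type = "weibull", shape = , scale = )` (hazard
#'   `(shape/scale) (t/scale)^(shape-1)`).
#' @param covariates List of per-covariate laws, one per coefficient:
#'   `list(type = "bernoulli", prob = )`, `list(type = "uniform", min = ,
#'   max = )`, or `list(type = "truncnorm", mean = , sd = , lower = ,
#'   upper = )`. Default: one Bernoulli(0.5) covariate per coefficient.
#' @param censoring `list(type = "none")`, `list(type = "exponential",
#'   rate = )` or `list(type = "uniform", max = )`; independent of the event
#'   time.
#' @param n Default sample size for [simulate_survival()].
#' @return A validated `survweight_dgp` list.
#' @examples
#' dgp_spec("ph", coef = 0.7, censoring = list(type = "exponential", rate = 0.3))
#' @export
dgp_spec <- function(model = c("ph", "ah"), coef,
                     baseline = list(type = "constant", rate = 1),
                     covariates = NULL,
                     censoring = list(type = "none"),
                     n = 500) {
  model <- match.arg(model)
  coef <- as.numeric(coef)
  p <- length(coef)
  if (p < 1 || any(!is.finite(coef))) {
    sw_abort("`coef` must be a finite vector", "survweight_error_input")
  }
  if (is.null(covariates)) {
    covariates <- replicate(p, list(type = "bernoulli", prob = 0.5),
                            simplify = FALSE)
  }
  if (length(covariates) != p) {
    sw_abort("need one covariate law per coefficient", "survweight_error_input")
  }
  for (cv in covariates) {
    if (!cv$type %in% c("bernoulli", "uniform", "truncnorm")) {
      sw_abort(paste0("unknown covariate law: ", cv$type), "survweight_error_input")
    }
  }
  if (!baseline$type %in% c("constant", "weibull")) {
    sw_abort("baseline type must be 'constant' or 'weibull'", "survweight_error_input")
  }
  if (baseline$type == "constant") {
    sw_stopifnot_scalar_num(baseline$rate, "baseline$rate", positive = TRUE)
  } else {
    sw_stopifnot_scalar_num(baseline$shape, "baseline$shape", positive = TRUE)
    sw_stopifnot_scalar_num(baseline$scale, "baseline$scale", positive = TRUE)
  }
  if (!censoring$type %in% c("none", "exponential", "uniform")) {
    sw_abort("censoring type must be 'none', 'exponential' or 'uniform'",
             "survweight_error_input")
  }

  spec <- structure(list(model = model, coef = coef, baseline = baseline,
                         covariates = covariates, censoring = censoring,
                         n = as.integer(n)),
                    class = "survweight_dgp")
  if (model == "ah") {
    # hazard must stay non-negative over the whole covariate support
    lam0_min <- if (baseline$type == "constant") baseline$rate else 0
    worst <- sum(vapply(seq_len(p), function(j) {
      s <- covariate_support(covariates[[j]])
      min(coef[j] * s)
    }, numeric(1)))
    if (lam0_min + worst < 0) {
      sw_abort(sprintf(
        "additive-hazards spec allows negative hazard (min lambda0 + min alpha'Z = %.4g)",
        lam0_min + worst), "survweight_error_invalid_dgp")
    }
  }
  spec
}

covariate_support <- function(cv) {
  switch(cv$type,
         bernoulli = c(0, 1),
         uniform = c(cv$min, cv$max),
         truncnorm = c(cv$lower, cv$upper))
}

draw_covariates <- function(covariates, n) {
  cols <- lapply(covariates, function(cv) {
    switch(cv$type,
           bernoulli = stats::rbinom(n, 1, cv$prob),
           uniform = stats::runif(n, cv$min, cv$max),
           truncnorm = {
             lo <- stats::pnorm(cv$lower, cv$mean, cv$sd)
             hi <- stats::pnorm(cv$upper, cv$mean, cv$sd)
             stats::qnorm(stats::runif(n, lo, hi), cv$mean, cv$sd)
           })
  })
  zm <- do.call(cbind, cols)
  colnames(zm) <- paste0("z", seq_along(covariates))
  zm
}

# cumulative baseline hazard and its inverse
baseline_cumhaz <- function(baseline, t) {
  if (baseline$type == "constant") baseline$rate * t
  else (t / baseline$scale)^baseline$shape
}

baseline_cumhaz_inv <- function(baseline, e) {
  if (baseline$type == "constant") e / baseline$rate
  else baseline$scale * e^(1 / baseline$shape)
}

true_cumhaz <- function(spec, t, zm) {
  lp <- drop(zm %*% spec$coef)
  if (spec$model == "ph") baseline_cumhaz(spec$baseline, t) * exp(lp)
  else baseline_cumhaz(spec$baseline, t) + lp * t
}

draw_event_times <- function(spec, zm) {
  n <- nrow(zm)
  lp <- drop(zm %*% spec$coef)
  e <- stats::rexp(n)                       # = -log U
  if (spec$model == "ph") {
    baseline_cumhaz_inv(spec$baseline, e * exp(-lp))
  } else if (spec$baseline$type == "constant") {
    e / (spec$baseline$rate + lp)
  } else {
    # solve (t/s)^a + lp * t = e per subject
    vapply(seq_len(n), function(i) {
      f <- function(t) baseline_cumhaz(spec$baseline, t) + lp[i] * t - e[i]
      upper <- baseline_cumhaz_inv(spec$baseline, e[i]) + e[i] / max(lp[i], 1e-12)
      stats::uniroot(f, c(0, max(upper, 1e-8)), tol = 1e-12)$root
    }, numeric(1))
  }
}

draw_censoring <- function(censoring, n) {
  switch(censoring$type,
         none = rep(Inf, n),
         exponential = stats::rexp(n, censoring$rate),
         uniform = stats::runif(n, 0, censoring$max))
}

#' Simulate a right-censored cohort from a DGP specification
#'
#' @param spec A [dgp_spec()].
#' @param n Sample size (default `spec$n`).
#' @param seed Optional integer seed (reproducible datasets).
#' @return A [surv_data()] tibble with covariates `z1..zp`, unit weights,
#'   and a hidden `latent_time` attribute is *not* kept: only the observed
#'   `(time, event, Z)` triples are returned.
#' @export
simulate_survival <- function(spec, n = spec$n, seed = NULL) {
  stopifnot(inherits(spec, "survweight_dgp"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  zm <- draw_covariates(spec$covariates, n)
  tt <- draw_event_times(spec, zm)
  cc <- draw_censoring(spec$censoring, n)
  x <- pmin(tt, cc)
  d <- as.integer(tt <= cc)
  df <- tibble::as_tibble(as.data.frame(zm))
  df$time <- x
  df$event <- d
  surv_data(df, time, event, covariates = colnames(zm))
}

#' Calibrate a censoring parameter to a target censoring fraction
#'
#' Finds the exponential rate (or uniform upper bound) giving a requested
#' marginal censoring fraction under the spec's event-time law, by Monte
#' Carlo evaluation of `P(C < T)` and root finding.
#'
#' @param spec A [dgp_spec()] whose `censoring$type` is `"exponential"` or
#'   `"uniform"`.
#' @param target Target censoring fraction in \[0, 0.95\].
#' @param n_mc Monte Carlo size for the latent event-time sample.
#' @param seed Seed for the calibration sample.
#' @return The spec with its censoring parameter set.
#' @export
calibrate_censoring <- function(spec, target, n_mc = 100000, seed = 1) {
  stopifnot(inherits(spec, "survweight_dgp"))
  if (!is.numeric(target) || target < 0 || target > 0.95) {
    sw_abort("target censoring fraction must be in [0, 0.95]",
             "survweight_error_input")
  }
  if (spec$censoring$type == "none") {
    sw_abort("spec has no censoring mechanism to calibrate",
             "survweight_error_input")
  }
  set.seed(as.integer(seed))
  zm <- draw_covariates(spec$covariates, n_mc)
  tt <- draw_event_times(spec, zm)
  cens_frac <- if (spec$censoring$type == "exponential") {
    function(par) mean(1 - exp(-par * tt))        # P(C < T | T), C ~ Exp(par)
  } else {
    function(par) mean(pmin(tt / par, 1))          # C ~ U(0, par)
  }
  f <- function(lpar) cens_frac(exp(lpar)) - target
  root <- stats::uniroot(f, c(-25, 25), tol = 1e-10)$root
  par <- exp(root)
  if (spec$censoring$type == "exponential") spec$censoring$rate <- par
  else spec$censoring$max <- par
  spec
}

#' External-model predictions for an analysis cohort
#'
#' Emulates the external-information setting: a prediction model is built on
#' an independent external cohort drawn from the same data-generating
#' process (optionally using only a subset of the covariates, i.e. a
#' misspecified external model), and its predictions at a horizon are
#' returned for every analysis subject on both scales (survival probability
#' and cumulative hazard). With `builder = "oracle_true"` the true model's
#' predictions are returned (no external-fit noise). With
#' `builder = "user_table"` the supplied predictions are passed through.
#'
#' @param analysis_data A [surv_data()] tibble (the local cohort).
#' @param dgp The [dgp_spec()] both cohorts are drawn from.
#' @param builder `"ph_fit"`, `"ah_fit"`, `"oracle_true"` or `"user_table"`.
#' @param horizon Prediction time.
#' @param covariate_subset Integer indices of the covariates the external
#'   model may use (default: all). A proper subset makes the external model
#'   misspecified.
#' @param external_n Size of the independent external cohort.
#' @param seed Seed for drawing the external cohort.
#' @param table For `builder = "user_table"`: a data frame with a
#'   `surv_prob` and/or `cum_haz` column, one row per analysis subject.
#' @return A tibble with columns `surv_prob` and `cum_haz` (consistent via
#'   `surv_prob = exp(-cum_haz)` for the model builders).
#' @export
external_predictions <- function(analysis_data, dgp,
                                 builder = c("ph_fit", "ah_fit", "oracle_true",
                                             "user_table"),
                                 horizon,
                                 covariate_subset = NULL,
                                 external_n = 500, seed = NULL, table = NULL) {
  builder <- match.arg(builder)
  if (builder == "user_table") {
    stopifnot(is.data.frame(table), nrow(table) == nrow(analysis_data))
    sp <- table$surv_prob %||% exp(-table$cum_haz)
    ch <- table$cum_haz %||% (-log(pmax(table$surv_prob, .Machine$double.xmin)))
    return(tibble::tibble(surv_prob = as.numeric(sp), cum_haz = as.numeric(ch)))
  }
  sw_stopifnot_scalar_num(horizon, "horizon", positive = TRUE)
  zm_new <- covariate_matrix(analysis_data)

  if (builder == "oracle_true") {
    H <- true_cumhaz(dgp, horizon, zm_new)
    return(tibble::tibble(surv_prob = exp(-H), cum_haz = H))
  }

  subset <- covariate_subset %||% seq_along(dgp$coef)
  if (length(subset) < 1) {
    sw_abort("covariate_subset must be non-empty", "survweight_error_input")
  }
  ext <- simulate_survival(dgp, n = external_n, seed = seed)
  cn <- covariate_names(ext)[subset]
  ext_sub <- surv_data(tibble::as_tibble(as.data.frame(ext)), time, event,
                       covariates = cn)
  zsub <- zm_new[, subset, drop = FALSE]

  if (builder == "ph_fit") {
    f <- cox_fit(ext_sub)
    bl <- breslow_baseline(f)
    L0h <- attr(bl, "fun")(horizon)
    H <- L0h * exp(drop(zsub %*% as.numeric(f$beta_hat)))
  } else {
    f <- linying_fit(ext_sub)
    bl <- linying_baseline(f)
    L0h <- attr(bl, "fun")(horizon)
    H <- pmax(L0h + drop(zsub %*% as.numeric(f$alpha_hat)) * horizon, 0)
  }
  tibble::tibble(surv_prob = exp(-H), cum_haz = H)
}

# turn a weight rule (string or function) + predictions into weights
apply_weight_rule <- function(rule, preds, horizon = NULL) {
  if (is.function(rule)) return(as_weights(rule(preds), horizon = horizon))
  switch(rule,
         none = as_weights(rep(1, nrow(preds)), source = "unit"),
         survival_prob = weights_from_survival_prob(preds$surv_prob, horizon),
         cumulative_hazard = weights_from_cumulative_hazard(preds$cum_haz, horizon),
         sw_abort(paste0("unknown weight rule: ", rule), "survweight_error_input"))
}

#' Monte Carlo least-false-parameter oracle
#'
#' Approximates the least-false parameter (the probability limit of the
#' weighted estimator under a possibly misspecified working model) by
#' solving the weighted estimating equation on one very large simulated
#' cohort, with weights built from the *true* model's predictions
#' (`builder = "oracle_true"`, removing external-fit noise). The Monte Carlo
#' standard error comes from refitting on disjoint blocks of the same
#' cohort.
#'
#' @param dgp A [dgp_spec()] (the truth).
#' @param weight_rule `"none"`, `"survival_prob"`, `"cumulative_hazard"`, or
#'   a function mapping the prediction tibble to a weight vector.
#' @param model Working model to fit: `"cox"` or `"additive"`.
#' @param horizon Prediction horizon for the weight rule.
#' @param n_oracle Simulated cohort size (default 200000).
#' @param seed Integer seed.
#' @param blocks Number of disjoint blocks for the MC standard error.
#' @return A list with `estimate` (the oracle beta*/alpha*), `mc_se`,
#'   `block_estimates`, `n_oracle`, `model`, `weight_rule`.
#' @export
least_false_oracle <- function(dgp, weight_rule = "none",
                               model = c("cox", "additive"),
                               horizon = NULL,
                               n_oracle = 200000, seed = 1, blocks = 20) {
  model <- match.arg(model)
  d <- simulate_survival(dgp, n = n_oracle, seed = seed)
  w <- if (identical(weight_rule, "none")) {
    as_weights(rep(1, nrow(d)), source = "unit")
  } else {
    preds <- external_predictions(d, dgp, builder = "oracle_true",
                                  horizon = horizon)
    apply_weight_rule(weight_rule, preds, horizon)
  }
  fit_one <- function(dd, ww) {
    if (model == "cox") as.numeric(cox_fit(dd, weights = ww)$beta_hat)
    else as.numeric(linying_fit(dd, weights = ww)$alpha_hat)
  }
  est <- fit_one(d, w)

  blk <- rep(seq_len(blocks), length.out = nrow(d))
  bl_est <- vapply(seq_len(blocks), function(bi) {
    idx <- which(blk == bi)
    dd <- surv_data(tibble::as_tibble(as.data.frame(d))[idx, ], time, event,
                    covariates = covariate_names(d))
    fit_one(dd, as.numeric(w)[idx])
  }, numeric(length(est)))
  bl_est <- matrix(bl_est, nrow = length(est))
  mc_se <- apply(bl_est, 1, stats::sd) / sqrt(blocks)

  list(estimate = stats::setNames(est, covariate_names(d)),
       mc_se = stats::setNames(mc_se, covariate_names(d)),
       block_estimates = t(bl_est),
       n_oracle = n_oracle, model = model,
       weight_rule = if (is.function(weight_rule)) "custom" else weight_rule)
}
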