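# Perturbation (multiplier) resampling: refit the weighted model B times with
# per-subject weights V_i * w_i, V_i iid Exp(1) (mean = variance = 1). The
# conditional spread of the perturbed estimates approximates the sampling
# distribution of the estimator around the least-false parameter, so
# percentile quantiles of the draws give confidence intervals.

#' Draw unit-mean exponential multipliers
#'
#' @param n Number of subjects (>= 1).
#' @return A length-`n` vector of iid Exp(1) draws (mean 1, variance 1),
#'   taken from the current RNG stream (use `set.seed()` or the `seed`
#'   argument of [perturbation_run()] for reproducibility).
#' @export
draw_multipliers <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    sw_abort("`n` must be a positive integer", "survweight_error_input")
  }
  stats::rexp(as.integer(n), rate = 1)
}

#' One perturbed refit
#'
#' Refits the model of a baseline fit with per-subject weights
#' `multipliers * w`, warm-started at the baseline estimate for Cox fits.
#' Non-convergence is flagged, not raised, so callers can count and drop
#' failed draws.
#'
#' @param fit A converged [cox_fit()] or [linying_fit()] object.
#' @param multipliers Positive multipliers, one per subject (in original
#'   row order).
#' @return A list with `estimate` (p-vector) and `converged` (logical).
#' @export
perturbed_fit <- function(fit, multipliers) {
  multipliers <- as.numeric(multipliers)
  if (length(multipliers) != fit$n) {
    sw_abort("need one multiplier per subject", "survweight_error_input")
  }
  prep <- fit$prep
  m_sorted <- multipliers[prep$ord]
  wG <- fit$w_used * m_sorted
  if (inherits(fit, "survweight_cox")) {
    res <- tryCatch(
      cox_newton(prep, wG, fit$ties, fit$weight_placement,
                 tol = fit$tol, max_iter = 100,
                 init = as.numeric(fit$beta_hat), static = fit$static),
      error = function(e) NULL)
    if (is.null(res) || !res$converged) {
      return(list(estimate = rep(NA_real_, prep$p), converged = FALSE))
    }
    list(estimate = res$beta, converged = TRUE)
  } else if (inherits(fit, "survweight_ah")) {
    eng <- ah_engine(prep, wG, fit$weight_placement, fit$tau)
    est <- tryCatch(drop(solve(eng$A, eng$b)), error = function(e) NULL)
    if (is.null(est) || any(!is.finite(est))) {
      return(list(estimate = rep(NA_real_, prep$p), converged = FALSE))
    }
    list(estimate = est, converged = TRUE)
  } else {
    sw_abort("`fit` must be a survweight_cox or survweight_ah object",
             "survweight_error_input")
  }
}

#' Perturbation-resampling inference
#'
#' Runs `B` perturbed refits with independent Exp(1) multiplier vectors,
#' then summarises the draws into perturbation standard errors (SD of the
#' draws) and percentile confidence intervals. Deterministic given
#' `(fit, B, seed)`. Draws that fail to converge are dropped and counted; an
#' error is raised if more than 10% fail (percentile validity degrades).
#'
#' @param fit A converged [cox_fit()] or [linying_fit()] object.
#' @param B Number of perturbation draws (default 1000).
#' @param seed Integer seed for the multiplier stream.
#' @param level Confidence level in (0, 1), default 0.95.
#' @return An object of class `survweight_perturb`: `draws` (B x p matrix,
#'   failed rows `NA`), `point_estimate`, `se`, `ci` (tibble with `term`,
#'   `lower`, `upper`), `B`, `seed`, `level`, `n_failed`. Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @examples
#' d <- simulate_survival(dgp_spec("ph", coef = 0.5, n = 150), seed = 2)
#' pr <- perturbation_run(cox_fit(d), B = 50, seed = 7)
#' tidy(pr)
#' @export
perturbation_run <- function(fit, B = 1000, seed = NULL, level = 0.95) {
  if (!is.numeric(B) || length(B) != 1L || B < 2) {
    sw_abort("`B` must be an integer >= 2", "survweight_error_input")
  }
  if (!fit$converged) {
    sw_abort("baseline fit did not converge", "survweight_error_nonconvergence")
  }
  B <- as.integer(B)
  n <- fit$n; p <- fit$prep$p
  if (!is.null(seed)) set.seed(as.integer(seed))

  draws <- matrix(NA_real_, B, p)
  for (b in seq_len(B)) {
    V <- draw_multipliers(n)
    pf <- perturbed_fit(fit, V)
    if (pf$converged) draws[b, ] <- pf$estimate
  }
  n_failed <- sum(!stats::complete.cases(draws))
  if (n_failed > 0.1 * B) {
    sw_abort(sprintf("%d of %d perturbed refits failed to converge (> 10%%)",
                     n_failed, B),
             "survweight_error_nonconvergence")
  }
  ok <- draws[stats::complete.cases(draws), , drop = FALSE]
  point <- if (inherits(fit, "survweight_cox")) fit$beta_hat else fit$alpha_hat
  cn <- fit$prep$covariates
  colnames(draws) <- cn
  ci <- percentile_ci(ok, level = level)
  ci$term <- cn

  structure(list(
    draws = draws, B = B, seed = seed, level = level,
    point_estimate = point,
    se = stats::setNames(apply(ok, 2, stats::sd), cn),
    ci = ci[, c("term", "lower", "upper")],
    n_failed = n_failed,
    model = if (inherits(fit, "survweight_cox")) "cox" else "additive"
  ), class = "survweight_perturb")
}

#' Percentile confidence intervals from resampled draws
#'
#' Per coefficient, the empirical `(1 - level)/2` and `1 - (1 - level)/2`
#' quantiles of the draws, using the linear-interpolation quantile definition
#' (`stats::quantile` type 7) so intervals are bit-reproducible.
#'
#' @param draws A B x p matrix (or vector) of resampled estimates.
#' @param level Confidence level strictly inside (0, 1).
#' @return A tibble with columns `term`, `lower`, `upper`.
#' @export
percentile_ci <- function(draws, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    sw_abort("`level` must be strictly between 0 and 1", "survweight_error_input")
  }
  draws <- as.matrix(draws)
  draws <- draws[stats::complete.cases(draws), , drop = FALSE]
  if (nrow(draws) < 1) {
    sw_abort("no draws available for percentile interval", "survweight_error_input")
  }
  a <- (1 - level) / 2
  qs <- apply(draws, 2, stats::quantile, probs = c(a, 1 - a),
              names = FALSE, type = 7)
  tibble::tibble(
    term = colnames(draws) %||% paste0("z", seq_len(ncol(draws))),
    lower = unname(qs[1, ]), upper = unname(qs[2, ])
  )
}

#' @export
print.survweight_perturb <- function(x, ...) {
  cat(sprintf(
    "<survweight_perturb> model = %s, B = %d (%d failed), level = %.2f%s\n",
    x$model, x$B, x$n_failed, x$level,
    if (is.null(x$seed)) "" else sprintf(", seed = %d", x$seed)))
  print(tidy(x))
  invisible(x)
}
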