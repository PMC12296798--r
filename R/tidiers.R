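# broom-style accessors and ggplot2 autoplot methods.

#' @rdname cox_fit
#' @param x A fitted object.
#' @param conf.int Add perturbation-free normal-approximation intervals based
#'   on the sandwich SE.
#' @param conf.level Level for `conf.int`.
#' @param ... Unused.
#' @method tidy survweight_cox
#' @export
tidy.survweight_cox <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  tidy_fit(x$beta_hat, x, conf.int, conf.level)
}

#' @rdname linying_fit
#' @param x A fitted object.
#' @param conf.int Add normal-approximation intervals based on the sandwich SE.
#' @param conf.level Level for `conf.int`.
#' @param ... Unused.
#' @method tidy survweight_ah
#' @export
tidy.survweight_ah <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  tidy_fit(x$alpha_hat, x, conf.int, conf.level)
}

tidy_fit <- function(est, x, conf.int, conf.level) {
  se <- sqrt(diag(x$sandwich_cov))
  out <- tibble::tibble(
    term = names(est),
    estimate = as.numeric(est),
    std.error = se,
    model.std.error = sqrt(diag(x$model_cov)),
    statistic = as.numeric(est) / se,
    p.value = 2 * stats::pnorm(-abs(as.numeric(est) / se))
  )
  if (conf.int) {
    z <- stats::qnorm(1 - (1 - conf.level) / 2)
    out$conf.low <- out$estimate - z * se
    out$conf.high <- out$estimate + z * se
  }
  out
}

#' @method glance survweight_cox
#' @export
glance.survweight_cox <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, loglik = x$loglik,
                 converged = x$converged, n_iter = x$n_iter,
                 score_norm = x$score_norm, ties = x$ties,
                 weight_placement = x$weight_placement)
}

#' @method glance survweight_ah
#' @export
glance.survweight_ah <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, converged = x$converged,
                 score_norm = x$score_norm, tau = x$tau,
                 weight_placement = x$weight_placement)
}

#' @rdname perturbation_run
#' @param x A `survweight_perturb` object.
#' @param ... Unused.
#' @method tidy survweight_perturb
#' @export
tidy.survweight_perturb <- function(x, ...) {
  tibble::tibble(
    term = x$ci$term,
    estimate = as.numeric(x$point_estimate),
    std.error = as.numeric(x$se),
    conf.low = x$ci$lower,
    conf.high = x$ci$upper
  )
}

#' @method glance survweight_perturb
#' @export
glance.survweight_perturb <- function(x, ...) {
  tibble::tibble(model = x$model, B = x$B, n_failed = x$n_failed,
                 level = x$level,
                 seed = if (is.null(x$seed)) NA_integer_ else x$seed)
}

#' Plot the perturbation distribution
#'
#' Histogram of the perturbed estimates per coefficient with the point
#' estimate (solid) and percentile interval (dashed) marked.
#'
#' @param object A `survweight_perturb` object.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot survweight_perturb
#' @export
autoplot.survweight_perturb <- function(object, bins = 40, ...) {
  long <- tibble::as_tibble(object$draws) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "term",
                        values_to = "estimate") |>
    dplyr::filter(is.finite(.data$estimate))
  marks <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$estimate)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(data = marks,
                        ggplot2::aes(xintercept = .data$estimate)) +
    ggplot2::geom_vline(data = marks, linetype = "dashed",
                        ggplot2::aes(xintercept = .data$conf.low)) +
    ggplot2::geom_vline(data = marks, linetype = "dashed",
                        ggplot2::aes(xintercept = .data$conf.high)) +
    ggplot2::facet_wrap(~term, scales = "free_x") +
    ggplot2::labs(x = "perturbed estimate", y = "count",
                  title = sprintf("Perturbation distribution (B = %d)", object$B))
}

#' Plot a baseline cumulative-hazard estimate
#'
#' @param object A `survweight_baseline` tibble (from [breslow_baseline()] or
#'   [linying_baseline()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot survweight_baseline
#' @export
autoplot.survweight_baseline <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$cum_haz)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time", y = "baseline cumulative hazard")
}

#' @rdname cox_fit
#' @param object A fitted `survweight_cox` object.
#' @method autoplot survweight_cox
#' @export
autoplot.survweight_cox <- function(object, ...) {
  autoplot.survweight_baseline(breslow_baseline(object)) +
    ggplot2::labs(title = "Aalen-Breslow baseline cumulative hazard")
}

#' @rdname linying_fit
#' @param object A fitted `survweight_ah` object.
#' @method autoplot survweight_ah
#' @export
autoplot.survweight_ah <- function(object, ...) {
  autoplot.survweight_baseline(linying_baseline(object)) +
    ggplot2::labs(title = "Additive-hazards baseline cumulative hazard")
}
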