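#' Weights from predicted survival probabilities
#'
#' The proportional-hazards weight recipe: an external risk model supplies a
#' predicted survival probability at a horizon (e.g. 5 years) for every
#' subject, and those probabilities are used directly as subject-specific
#' weights. Set `complement = TRUE` to weight by predicted event risk
#' `1 - S(horizon)` instead, which up-weights high-risk subjects.
#'
#' @param surv_probs Numeric vector of predicted survival probabilities in
#'   \[0, 1\].
#' @param horizon The prediction horizon (same time units as the analysis
#'   data); recorded as provenance.
#' @param complement If `TRUE`, use `1 - surv_probs`.
#' @return A numeric weight vector of class `survweight_weights` with
#'   attributes `source` (`"survival_prob"`) and `horizon`.
#' @examples
#' weights_from_survival_prob(c(0.9, 0.5, 0.1), horizon = 5)
#' @export
weights_from_survival_prob <- function(surv_probs, horizon = NULL,
                                       complement = FALSE) {
  surv_probs <- as.numeric(surv_probs)
  if (any(!is.finite(surv_probs)) ||
      any(surv_probs < 0) || any(surv_probs > 1)) {
    sw_abort("survival probabilities must be finite and in [0, 1]",
             "survweight_error_input")
  }
  if (!is.null(horizon)) sw_stopifnot_scalar_num(horizon, "horizon", positive = TRUE)
  vals <- if (complement) 1 - surv_probs else surv_probs
  new_weights(vals, source = "survival_prob", horizon = horizon)
}

#' Weights from predicted cumulative hazards
#'
#' The machine-learning (e.g. random survival forest) weight recipe: an
#' external model supplies a predicted cumulative hazard `H` at a horizon.
#' Weights are placed on the probability-of-event scale through
#' `w = 1 - exp(-H)`, so they live in \[0, 1) and are commensurable with the
#' survival-probability recipe; larger predicted hazard means larger weight.
#' Set `complement = TRUE` for `exp(-H)` (the implied survival probability).
#'
#' @param cum_haz Non-negative numeric vector of predicted cumulative hazards
#'   at the horizon.
#' @inheritParams weights_from_survival_prob
#' @return A `survweight_weights` vector with `source = "cumulative_hazard"`.
#' @examples
#' weights_from_cumulative_hazard(c(0, log(2), 2), horizon = 5)
#' @export
weights_from_cumulative_hazard <- function(cum_haz, horizon = NULL,
                                           complement = FALSE) {
  cum_haz <- as.numeric(cum_haz)
  if (any(!is.finite(cum_haz)) || any(cum_haz < 0)) {
    sw_abort("cumulative hazards must be finite and non-negative",
             "survweight_error_input")
  }
  if (!is.null(horizon)) sw_stopifnot_scalar_num(horizon, "horizon", positive = TRUE)
  risk <- 1 - exp(-cum_haz)
  vals <- if (complement) 1 - risk else risk
  new_weights(vals, source = "cumulative_hazard", horizon = horizon)
}

#' Coerce a numeric vector to a weight vector
#'
#' @param x Non-negative finite numeric vector, not all zero.
#' @param source Provenance label (default `"user"`).
#' @param horizon Optional prediction horizon.
#' @return A `survweight_weights` vector.
#' @export
as_weights <- function(x, source = "user", horizon = NULL) {
  new_weights(as.numeric(x), source = source, horizon = horizon)
}

new_weights <- function(values, source, horizon = NULL) {
  if (any(!is.finite(values)) || any(values < 0)) {
    sw_abort("weights must be finite and non-negative", "survweight_error_input")
  }
  if (length(values) > 0 && all(values == 0)) {
    sw_abort("at least one weight must be positive", "survweight_error_input")
  }
  structure(values, source = source, horizon = horizon,
            class = c("survweight_weights", "numeric"))
}

#' Rescale weights to mean one
#'
#' Both estimating equations are homogeneous of degree one in the weights, so
#' this rescaling (`w * n / sum(w)`) changes no point estimate; it only makes
#' weight magnitudes comparable across analyses.
#'
#' @param w A `survweight_weights` vector (or plain numeric weights).
#' @return Rescaled weights with mean exactly one, same provenance.
#' @export
normalize_weights <- function(w) {
  vals <- as.numeric(w)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    sw_abort("weights must be finite and non-negative", "survweight_error_input")
  }
  s <- sum(vals)
  if (s == 0) sw_abort("cannot normalize all-zero weights", "survweight_error_input")
  new_weights(vals * length(vals) / s,
              source = attr(w, "source") %||% "user",
              horizon = attr(w, "horizon"))
}

#' @export
print.survweight_weights <- function(x, ...) {
  cat(sprintf("<survweight_weights> n = %d, source = %s%s\n",
              length(x), attr(x, "source"),
              if (is.null(attr(x, "horizon"))) "" else
                sprintf(", horizon = %g", attr(x, "horizon"))))
  print(as.numeric(x), ...)
  invisible(x)
}

# resolve the weight vector to use for a fit: explicit argument wins,
# otherwise the dataset's weight column
resolve_weights <- function(data, weights) {
  if (is.null(weights)) {
    w <- data$weight
  } else {
    w <- as.numeric(weights)
    if (length(w) != nrow(data)) {
      sw_abort("`weights` must have one value per subject", "survweight_error_input")
    }
  }
  if (any(!is.finite(w)) || any(w < 0) || all(w == 0)) {
    sw_abort("weights must be finite, non-negative, and not all zero",
             "survweight_error_input")
  }
  w
}
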