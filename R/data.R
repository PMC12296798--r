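#' Build a weighted right-censored survival dataset
#'
#' Standardises a data frame of right-censored observations into the tibble
#' layout the fitting functions expect: a `time` column (follow-up time
#' `X = min(T, C)`), an `event` column (`1` if the event was observed, `0` if
#' censored), one column per covariate, and a `weight` column (subject-specific
#' weight, default 1). Covariate names, the analysis horizon `tau` and the
#' weight provenance are carried as attributes.
#'
#' @param data A data frame with one row per subject.
#' @param time,event Columns (tidy-eval) holding follow-up time and the
#'   0/1 event indicator.
#' @param covariates Character vector of covariate column names. May be
#'   empty for covariate-free summaries, but the fitters require at least one.
#' @param weights Optional: a column (tidy-eval) of per-subject weights, or a
#'   numeric vector of length `nrow(data)` (e.g. a [weights_from_survival_prob()]
#'   result). Default: all ones (unweighted analysis).
#' @param tau Analysis horizon; defaults to the largest observed time.
#'
#' @return A tibble of class `survweight_data` with columns `time`, `event`,
#'   the covariates, and `weight`; attributes `covariates` and `tau`.
#' @examples
#' d <- tibble::tibble(time = c(1, 2, 3), status = c(1, 0, 1), z = c(0, 1, 1))
#' surv_data(d, time, status, covariates = "z")
#' @export
surv_data <- function(data, time, event, covariates = character(),
                      weights = NULL, tau = NULL) {
  stopifnot(is.data.frame(data))
  tq <- rlang::enquo(time)
  eq <- rlang::enquo(event)
  t_vals <- as.numeric(rlang::eval_tidy(tq, data))
  e_vals <- as.numeric(rlang::eval_tidy(eq, data))

  covariates <- as.character(covariates)
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov) > 0) {
    sw_abort(paste0("Covariate column(s) not found: ",
                    paste(missing_cov, collapse = ", ")),
             "survweight_error_missing_column")
  }

  wq <- rlang::enquo(weights)
  if (rlang::quo_is_null(wq)) {
    w_vals <- rep(1, nrow(data))
    w_source <- "unit"
  } else {
    w_raw <- rlang::eval_tidy(wq, data)
    w_vals <- as.numeric(w_raw)
    w_source <- attr(w_raw, "source") %||% "user"
  }
  if (length(w_vals) != nrow(data)) {
    sw_abort("`weights` must have one value per row of `data`.",
             "survweight_error_input")
  }
  if (any(is.finite(w_vals) & w_vals == 0)) {
    rlang::warn(sprintf(
      "%d subject(s) have weight exactly 0; they are retained but contribute nothing.",
      sum(w_vals == 0, na.rm = TRUE)))
  }

  out <- tibble::tibble(time = t_vals, event = e_vals)
  for (cv in covariates) out[[cv]] <- as.numeric(data[[cv]])
  out$weight <- w_vals

  if (is.null(tau)) tau <- suppressWarnings(max(t_vals, na.rm = TRUE))

  structure(out,
            covariates = covariates,
            tau = as.numeric(tau),
            weight_source = w_source,
            class = c("survweight_data", class(out)))
}

covariate_names <- function(data) attr(data, "covariates")

covariate_matrix <- function(data) {
  cn <- covariate_names(data)
  m <- as.matrix(as.data.frame(data)[, cn, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a survival dataset
#'
#' Checks the structural invariants the estimation theory needs: finite
#' non-negative times, a 0/1 event indicator with at least one event,
#' bounded (finite) covariates, finite non-negative weights not all zero,
#' at least two subjects, and a positive horizon. Violations are reported,
#' not raised, so callers can present them all at once.
#'
#' @param data A [surv_data()] tibble.
#' @return A tibble with columns `field` and `message`, one row per violation;
#'   zero rows when the dataset is valid.
#' @export
validate_dataset <- function(data) {
  v <- list()
  add <- function(field, message) {
    v[[length(v) + 1L]] <<- tibble::tibble(field = field, message = message)
  }

  if (!inherits(data, "survweight_data")) {
    add("class", "not a survweight_data object (use surv_data())")
    return(dplyr::bind_rows(v))
  }
  n <- nrow(data)
  if (n < 2) add("n", "fewer than 2 records")

  tm <- data$time
  if (any(!is.finite(tm))) add("time", "non-finite follow-up time")
  if (any(is.finite(tm) & tm < 0)) add("time", "negative follow-up time")

  ev <- data$event
  if (any(!ev %in% c(0, 1))) add("event", "event indicator not in {0, 1}")
  if (!any(ev == 1, na.rm = TRUE)) add("event", "no events")

  zm <- covariate_matrix(data)
  if (length(zm) > 0 && any(!is.finite(zm))) {
    add("covariates", "non-finite covariate value")
  }

  w <- data$weight
  if (any(!is.finite(w))) add("weight", "non-finite weight")
  if (any(is.finite(w) & w < 0)) add("weight", "negative weight")
  if (all(w == 0, na.rm = TRUE)) add("weight", "all weights zero")

  tau <- attr(data, "tau")
  if (!is.finite(tau) || tau <= 0) add("tau", "tau must be a positive number")

  if (length(v) == 0) {
    tibble::tibble(field = character(), message = character())
  } else {
    dplyr::bind_rows(v)
  }
}

assert_valid_dataset <- function(data) {
  viol <- validate_dataset(data)
  if (nrow(viol) > 0) {
    sw_abort(paste0("Invalid dataset: ",
                    paste(viol$message, collapse = "; ")),
             "survweight_error_invalid_data")
  }
  invisible(data)
}

#' Risk-set index over distinct event times
#'
#' For each distinct event time, lists the subjects at risk (those with
#' `time >= t`; at tied times, events and censorings alike are still in the
#' risk set) and the subjects whose event occurs at that time. This is the
#' counting-process skeleton behind every risk-set sum.
#'
#' @param data A valid [surv_data()] tibble.
#' @return A tibble with columns `time` (strictly increasing distinct event
#'   times), `at_risk` (list of integer row indices), and `events` (list of
#'   integer row indices of events at that time).
#' @export
risk_index <- function(data) {
  assert_valid_dataset(data)
  ev_times <- sort(unique(data$time[data$event == 1]))
  tibble::tibble(
    time = ev_times,
    at_risk = lapply(ev_times, function(t) which(data$time >= t)),
    events = lapply(ev_times, function(t) which(data$time == t & data$event == 1))
  )
}

# Internal sorted representation shared by the fitters. Sorting is by time
# ascending; risk sums are reverse cumulative sums over this order, so record
# order in the input never influences any estimate.
fit_prep <- function(data) {
  assert_valid_dataset(data)
  zm <- covariate_matrix(data)
  if (ncol(zm) < 1) {
    sw_abort("at least one covariate is required for fitting",
             "survweight_error_input")
  }
  ord <- order(data$time, -data$event)  # events before censorings at ties
  tt <- data$time[ord]
  ee <- data$event[ord]
  ww <- data$weight[ord]
  zz <- zm[ord, , drop = FALSE]

  first_of_block <- !duplicated(tt)
  block_start <- which(first_of_block)              # index of first row per distinct time
  block_id <- cumsum(first_of_block)                # distinct-time id per row
  u_times <- tt[first_of_block]

  ev_rows <- which(ee == 1)
  ev_block <- block_id[ev_rows]
  ev_utimes <- sort(unique(ev_block))               # distinct-time ids holding events

  list(
    n = nrow(data), p = ncol(zm), ord = ord,
    time = tt, event = ee, w = ww, Z = zz,
    u_times = u_times, block_start = block_start, block_id = block_id,
    ev_rows = ev_rows, ev_block = ev_block, ev_blocks = ev_utimes,
    tau = attr(data, "tau"),
    covariates = covariate_names(data)
  )
}

#' @export
print.survweight_data <- function(x, ...) {
  cat(sprintf(
    "<survweight_data> %d subjects, %d events, %d covariate(s) [%s], tau = %g\n",
    nrow(x), sum(x$event == 1), length(covariate_names(x)),
    paste(covariate_names(x), collapse = ", "), attr(x, "tau")))
  NextMethod()
}
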