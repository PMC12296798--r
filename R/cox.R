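# Weighted proportional-hazards estimation.
#
# The weighted log partial likelihood is
#   l(b) = sum_i w_i d_i [ b'Z_i - log S0(b, X_i) ],
# with S0(b, t) = sum_j w_j I(X_j >= t) exp(b'Z_j) under the case-weight
# convention (weights in both event and risk-set sums), or the unweighted
# risk sum under weight_placement = "events-only". Efron's tie correction
# deducts the tied deaths' own risk contributions in fractional steps; the
# Breslow variant is the same computation with all fractions zero.

# Per-beta engine: log partial likelihood, score (total U_c) and observed
# information (total, i.e. not divided by n). All risk-set sums are reverse
# cumulative sums over the time-sorted order, so cost is O(n p^2) per call.
# Per-fit cache of beta-independent quantities (event groups, tie structure,
# covariate cross-products). Built once per (dataset, weight) pair and reused
# across Newton iterations and perturbation refits.
cox_static <- function(prep, ties) {
  p <- prep$p
  Z <- prep$Z
  ia <- rep(seq_len(p), times = p)
  ib <- rep(seq_len(p), each = p)
  Zsq <- Z[, ia, drop = FALSE] * Z[, ib, drop = FALSE]

  gb <- prep$ev_blocks
  k <- prep$block_start[gb]
  ev <- prep$ev_rows
  gmatch <- match(prep$ev_block, gb)
  d_g <- as.numeric(rowsum(rep(1, length(ev)), gmatch))
  if (ties == "efron") {
    frac_list <- lapply(d_g, function(dd) (seq_len(dd) - 1) / dd)
  } else {
    frac_list <- lapply(d_g, function(dd) rep(0, dd))
  }
  gidx <- rep(seq_along(gb), times = d_g)
  frac <- unlist(frac_list, use.names = FALSE)

  list(p = p, ia = ia, ib = ib, Zsq = Zsq, gb = gb, k = k, ev = ev,
       Zev = Z[ev, , drop = FALSE], Zsqev = Zsq[ev, , drop = FALSE],
       gmatch = gmatch, d_g = d_g, gidx = gidx, frac = frac,
       any_frac = any(frac > 0), ties = ties)
}

# add the weight-dependent pieces to the static cache
cox_cache <- function(prep, w, ties, static = NULL) {
  cache <- static %||% cox_static(prep, ties)
  w_ev <- w[cache$ev]
  dW <- as.numeric(rowsum(w_ev, cache$gmatch))
  wbar <- dW / cache$d_g
  cache$w_ev <- w_ev
  cache$dW <- dW
  cache$dWZ_tot <- colSums(w_ev * cache$Zev)
  cache$wbar <- wbar
  cache$wsub <- wbar[cache$gidx]
  cache
}

# column-wise reverse cumulative sums without apply() overhead
rcs_cols <- function(m) {
  for (j in seq_len(ncol(m))) m[, j] <- revcumsum(m[, j])
  m
}

# Log partial likelihood, score and observed information (all totals) at
# beta. derivs = FALSE computes the likelihood only (step-halving probes).
cox_engine2 <- function(prep, w, beta, cache, placement, derivs = TRUE) {
  Z <- prep$Z
  eta <- drop(Z %*% beta)
  cc <- max(eta)                      # centering guards exp overflow
  rr <- exp(eta - cc)
  rw <- if (placement == "both") w * rr else rr

  rc0 <- revcumsum(rw)
  gidx <- cache$gidx
  S0e <- rc0[cache$k]
  ev <- cache$ev

  if (cache$any_frac) {
    rw_ev <- rw[ev]
    e0 <- as.numeric(rowsum(rw_ev, cache$gmatch))
    s0k <- S0e[gidx] - cache$frac * e0[gidx]
  } else {
    s0k <- S0e[gidx]
  }
  if (any(!is.finite(s0k)) || any(s0k <= 0)) {
    sw_abort("risk-set sum overflow/underflow in exp(beta'Z); beta too extreme",
             "survweight_error_overflow")
  }
  loglik <- sum(cache$w_ev * (eta[ev] - cc)) - sum(cache$wsub * log(s0k))
  if (!derivs) return(list(loglik = loglik))

  rc1 <- rcs_cols(rw * Z)
  rc2 <- rcs_cols(rw * cache$Zsq)
  S1e <- rc1[cache$k, , drop = FALSE]
  S2e <- rc2[cache$k, , drop = FALSE]
  if (cache$any_frac) {
    e1 <- rowsum(rw_ev * cache$Zev, cache$gmatch)
    e2 <- rowsum(rw_ev * cache$Zsqev, cache$gmatch)
    s1k <- S1e[gidx, , drop = FALSE] - cache$frac * e1[gidx, , drop = FALSE]
    s2k <- S2e[gidx, , drop = FALSE] - cache$frac * e2[gidx, , drop = FALSE]
  } else {
    s1k <- S1e[gidx, , drop = FALSE]
    s2k <- S2e[gidx, , drop = FALSE]
  }
  mk <- s1k / s0k
  wsub <- cache$wsub
  p <- cache$p
  score <- cache$dWZ_tot - colSums(wsub * mk)
  info <- matrix(colSums(wsub * (s2k / s0k - mk[, cache$ia, drop = FALSE] *
                                   mk[, cache$ib, drop = FALSE])), p, p)

  list(loglik = loglik, score = score, info = info,
       sub = list(gb = cache$gb, k = cache$k, gidx = gidx, frac = cache$frac,
                  s0k = s0k, mk = mk, wsub = wsub, dW = cache$dW,
                  d_g = cache$d_g, wbar = cache$wbar, rw = rw,
                  gmatch = cache$gmatch))
}

# compatibility wrapper used by cox_score() / breslow_baseline()
cox_engine <- function(prep, w, beta, ties, placement) {
  cox_engine2(prep, w, beta, cox_cache(prep, w, ties), placement)
}

cox_newton <- function(prep, w, ties, placement, tol, max_iter, init = NULL,
                       beta_max = 50, static = NULL) {
  p <- prep$p
  cache <- cox_cache(prep, w, ties, static)
  beta <- if (is.null(init)) rep(0, p) else as.numeric(init)
  eng <- cox_engine2(prep, w, beta, cache, placement)
  n_iter <- 0L
  converged <- max(abs(eng$score)) <= tol
  while (!converged && n_iter < max_iter) {
    step <- tryCatch(solve(eng$info, eng$score), error = function(e) {
      sw_abort("singular information matrix (collinear covariates?)",
               "survweight_error_singular")
    })
    accepted <- FALSE
    for (h in 0:20) {                 # step-halving keeps the likelihood monotone
      cand <- beta + step / 2^h
      ll <- tryCatch(
        cox_engine2(prep, w, cand, cache, placement, derivs = FALSE)$loglik,
        error = function(e) NA_real_)
      if (is.finite(ll) && ll >= eng$loglik - 1e-12 * (abs(eng$loglik) + 1)) {
        beta <- cand
        eng <- cox_engine2(prep, w, beta, cache, placement)
        accepted <- TRUE
        break
      }
    }
    n_iter <- n_iter + 1L
    if (!accepted) break
    if (max(abs(beta)) > beta_max) {
      sw_abort("estimates diverging (monotone likelihood / separation?)",
               "survweight_error_nonconvergence")
    }
    converged <- max(abs(eng$score)) <= tol
  }
  list(beta = beta, eng = eng, converged = converged, n_iter = n_iter,
       score_norm = max(abs(eng$score)))
}

#' Weighted Cox partial-likelihood score
#'
#' Evaluates the weighted estimating function
#' `U(b) = sum_i w_i d_i { Z_i - S1(b, X_i) / S0(b, X_i) }` at a given
#' coefficient vector, with the tie correction and weight placement requested.
#'
#' @param beta Coefficient vector (length = number of covariates).
#' @param data A [surv_data()] tibble.
#' @param weights Optional per-subject weights overriding the dataset's
#'   `weight` column.
#' @param ties `"efron"` (default) or `"breslow"` tie handling.
#' @param weight_placement `"both"` (case-weight convention: weights in event
#'   and risk-set sums, the default) or `"events-only"` (weights on event terms
#'   only, risk sums unweighted).
#' @return Named numeric score vector.
#' @export
cox_score <- function(beta, data, weights = NULL,
                      ties = c("efron", "breslow"),
                      weight_placement = c("both", "events-only")) {
  ties <- match.arg(ties)
  weight_placement <- match.arg(weight_placement)
  prep <- fit_prep(data)
  w <- resolve_weights(data, weights)[prep$ord]
  sc <- cox_engine(prep, w, as.numeric(beta), ties, weight_placement)$score
  stats::setNames(sc, prep$covariates)
}

#' Fit a weighted Cox proportional-hazards model
#'
#' Maximises the weighted log partial likelihood by Newton-Raphson with
#' step-halving. Under an external-prediction weight vector the estimand is
#' the least-false parameter of the proportional-hazards working model, so
#' the returned object carries both the model-based covariance (inverse
#' information) and the model-robust sandwich covariance; use
#' [perturbation_run()] for resampling-based intervals.
#'
#' @inheritParams cox_score
#' @param tol Convergence tolerance on the infinity norm of the score.
#' @param max_iter Maximum Newton iterations.
#' @param init Optional starting value (default zero).
#' @return An object of class `survweight_cox`: a list with `beta_hat`,
#'   `loglik`, `info` (A-hat, observed information / n), `meat` (B-hat),
#'   `model_cov`, `sandwich_cov`, `converged`, `n_iter`, `score_norm`, and
#'   bookkeeping fields. Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' spec <- dgp_spec("ph", coef = 0.7, n = 200)
#' d <- simulate_survival(spec, seed = 1)
#' fit <- cox_fit(d)
#' tidy(fit)
#' @export
cox_fit <- function(data, weights = NULL, ties = c("efron", "breslow"),
                    weight_placement = c("both", "events-only"),
                    tol = 1e-9, max_iter = 100, init = NULL) {
  ties <- match.arg(ties)
  weight_placement <- match.arg(weight_placement)
  prep <- fit_prep(data)
  w <- resolve_weights(data, weights)[prep$ord]
  static <- cox_static(prep, ties)

  nt <- cox_newton(prep, w, ties, weight_placement, tol, max_iter, init,
                   static = static)
  n <- prep$n; p <- prep$p
  info_tot <- nt$eng$info
  model_cov <- tryCatch(solve(info_tot), error = function(e) {
    sw_abort("singular information matrix at the optimum",
             "survweight_error_singular")
  })
  V <- cox_score_residuals(prep, w, nt$eng)
  meat_tot <- crossprod(V)
  sandwich_cov <- model_cov %*% meat_tot %*% model_cov

  cn <- prep$covariates
  dimnames(model_cov) <- dimnames(sandwich_cov) <- list(cn, cn)
  structure(list(
    beta_hat = stats::setNames(nt$beta, cn),
    loglik = nt$eng$loglik,
    score = stats::setNames(nt$eng$score, cn),
    score_norm = nt$score_norm,
    info = info_tot / n,
    meat = meat_tot / n,
    model_cov = model_cov,
    sandwich_cov = sandwich_cov,
    residuals = V,
    converged = nt$converged,
    n_iter = nt$n_iter,
    n = n, n_events = length(prep$ev_rows),
    ties = ties, weight_placement = weight_placement,
    tol = tol,
    data = data, w_used = w, prep = prep, static = static
  ), class = "survweight_cox")
}

# Per-subject score residuals V_i (rows ordered as prep, i.e. time-sorted):
# event term minus the subject's accumulated risk-set contribution over
# event times at which it is at risk. sum_i V_i = U(beta-hat) = 0.
cox_score_residuals <- function(prep, w, eng) {
  n <- prep$n; p <- prep$p
  Z <- prep$Z
  sub <- eng$sub
  G <- length(sub$gb)

  inv0 <- sub$wsub / sub$s0k
  A_g <- as.numeric(rowsum(inv0, sub$gidx))                       # G
  Am_g <- rowsum(inv0 * sub$mk, sub$gidx)                         # G x p
  onefrac <- 1 - sub$frac
  Ad_g <- as.numeric(rowsum(inv0 * onefrac, sub$gidx))
  Adm_g <- rowsum(inv0 * onefrac * sub$mk, sub$gidx)
  mbar_g <- rowsum(sub$mk, sub$gidx) / sub$d_g                    # G x p

  ev_times <- prep$u_times[sub$gb]
  cnt <- findInterval(prep$time, ev_times)                        # events <= t_i
  cumA <- c(0, cumsum(A_g))
  cumAm <- rbind(0, apply(Am_g, 2, cumsum))
  if (p == 1) cumAm <- matrix(cumAm, ncol = 1)

  P <- cumA[cnt + 1L]
  Q <- cumAm[cnt + 1L, , drop = FALSE]

  ev <- prep$ev_rows
  g_of_ev <- sub$gmatch
  # deaths at their own event time use the Efron-deflated accumulation
  P[ev] <- P[ev] + (Ad_g - A_g)[g_of_ev]
  Q[ev, ] <- Q[ev, , drop = FALSE] + (Adm_g - Am_g)[g_of_ev, , drop = FALSE]

  evterm <- matrix(0, n, p)
  evterm[ev, ] <- w[ev] * (Z[ev, , drop = FALSE] - mbar_g[g_of_ev, , drop = FALSE])

  evterm - sub$rw * (Z * P - Q)
}

#' Model-robust (sandwich) covariance of a weighted Cox fit
#'
#' Returns the covariance estimate `A^-1 B A^-1 / n` built from the observed
#' information (bread) and the outer products of per-subject weighted score
#' residuals (meat). Valid for the least-false parameter even when the
#' proportional-hazards working model is misspecified.
#'
#' @param fit A [cox_fit()] object (must have converged).
#' @return A p x p covariance matrix for `beta_hat`.
#' @export
cox_sandwich <- function(fit) {
  stopifnot(inherits(fit, "survweight_cox"))
  if (!fit$converged) {
    sw_abort("sandwich covariance requires a converged fit",
             "survweight_error_nonconvergence")
  }
  fit$sandwich_cov
}

#' Aalen-Breslow baseline cumulative hazard
#'
#' Step-function estimate `L0(t) = sum_{event times s <= t} dW(s) / S0(b, s)`
#' at the fitted coefficients, with `dW` the weighted event mass and `S0`
#' the (placement-consistent) weighted risk sum. Reduces to the Nelson-Aalen
#' estimator when `beta_hat = 0` and all weights are one.
#'
#' @param fit A converged [cox_fit()] object.
#' @return A tibble of class `survweight_baseline` with columns `time` and
#'   `cum_haz`; the attribute `fun` is a right-continuous step function
#'   evaluating the estimate at arbitrary times.
#' @export
breslow_baseline <- function(fit) {
  stopifnot(inherits(fit, "survweight_cox"))
  if (!fit$converged) {
    sw_abort("baseline estimation requires a converged fit",
             "survweight_error_nonconvergence")
  }
  prep <- fit$prep
  eng <- cox_engine(prep, fit$w_used, as.numeric(fit$beta_hat),
                    fit$ties, fit$weight_placement)
  sub <- eng$sub
  S0e <- sub$s0k[!duplicated(sub$gidx)]       # full risk sum per event time
  if (any(S0e <= 0)) {
    sw_abort("zero risk-set sum at an event time", "survweight_error_input")
  }
  inc <- sub$dW / S0e
  tt <- prep$u_times[sub$gb]
  ch <- cumsum(inc)
  out <- tibble::tibble(time = tt, cum_haz = ch)
  attr(out, "fun") <- stats::stepfun(tt, c(0, ch), right = FALSE)
  class(out) <- c("survweight_baseline", class(out))
  out
}

#' @export
print.survweight_cox <- function(x, ...) {
  cat(sprintf(
    "<survweight_cox> n = %d, events = %d, ties = %s, placement = %s\n",
    x$n, x$n_events, x$ties, x$weight_placement))
  cat(sprintf("converged: %s after %d iteration(s); ||score||_inf = %.3g\n",
              x$converged, x$n_iter, x$score_norm))
  print(tidy(x))
  invisible(x)
}
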