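# Weighted Lin-Ying additive-hazards estimation.
#
# Under lambda(t|Z) = lambda0(t) + alpha'Z, the weighted estimating function
#   U1(a) = sum_i w_i int_0^tau (Z_i - zbar(t)) { dN_i(t) - Y_i(t) a'Z_i dt }
# is linear in a, so alpha-hat = A^-1 b with
#   A = sum_i w_i int_0^tau Y_i(t) (Z_i - zbar(t)) Z_i' dt,
#   b = sum_i w_i d_i (Z_i - zbar(X_i)) I(X_i <= tau).
# zbar(t) is the weighted at-risk covariate mean under the default case-weight
# convention, the unweighted mean under weight_placement = "events-only".
# All t-integrals are exact sums over the inter-exit-time step structure
# (the integrands are piecewise constant between observed times).

ah_engine <- function(prep, w, placement, tau) {
  n <- prep$n; p <- prep$p
  Z <- prep$Z
  vw <- if (placement == "both") w else rep(1, n)     # zbar / baseline weights

  rcw0 <- revcumsum(w)
  rcwZ <- revcumsum_mat(w * Z)
  ia <- rep(seq_len(p), times = p)
  ib <- rep(seq_len(p), each = p)
  Zsq <- Z[, ia, drop = FALSE] * Z[, ib, drop = FALSE]
  rcwZZ <- revcumsum_mat(w * Zsq)
  rcv0 <- revcumsum(vw)
  rcvZ <- revcumsum_mat(vw * Z)

  ks <- prep$block_start
  u <- prep$u_times
  Sw0 <- rcw0[ks]; SwZ <- rcwZ[ks, , drop = FALSE]
  SwZZ <- rcwZZ[ks, , drop = FALSE]
  Sv0 <- rcv0[ks]; SvZ <- rcvZ[ks, , drop = FALSE]
  zbar <- SvZ / Sv0                                   # K x p

  # interval (u_{k-1}, u_k] clipped to [0, tau]
  lo <- c(0, head(u, -1))
  delta <- pmax(pmin(u, tau) - pmin(lo, tau), 0)

  # A = sum_k delta_k [ SwZZ_k - zbar_k (x) SwZ_k ]
  Amat <- matrix(colSums(delta * (SwZZ - zbar[, ia, drop = FALSE] *
                                    SwZ[, ib, drop = FALSE])), p, p)

  ev <- prep$ev_rows[prep$time[prep$ev_rows] <= tau]
  blk <- prep$block_id[ev]
  resid_ev <- Z[ev, , drop = FALSE] - zbar[blk, , drop = FALSE]
  b <- colSums(w[ev] * resid_ev)

  list(A = Amat, b = b, zbar = zbar, delta = delta, u = u,
       Sw0 = Sw0, SwZ = SwZ, Sv0 = Sv0,
       ev = ev, ev_blk = blk, resid_ev = resid_ev, vw = vw)
}

#' Fit a weighted Lin-Ying additive-hazards model
#'
#' Closed-form weighted least-squares-type estimation of the constant
#' coefficient vector in the semiparametric additive-hazards model
#' `lambda(t|Z) = lambda0(t) + alpha'Z`. With external-prediction weights the
#' estimand is the least-false parameter of this working model; the object
#' carries the martingale-based model covariance and the model-robust
#' sandwich covariance `D^-1 E D^-1 / n`.
#'
#' @inheritParams cox_score
#' @param tau Analysis horizon; integration stops here. Defaults to the
#'   dataset's `tau` attribute (largest observed time).
#' @return An object of class `survweight_ah`: a list with `alpha_hat`,
#'   `D_hat` (slope matrix of the estimating function / n), `E_hat`,
#'   `model_cov`, `sandwich_cov`, `converged` (always `TRUE`: closed form),
#'   `score_norm`, and bookkeeping fields.
#' @examples
#' spec <- dgp_spec("ah", coef = 0.5, baseline = list(type = "constant", rate = 1),
#'                  n = 300)
#' d <- simulate_survival(spec, seed = 1)
#' tidy(linying_fit(d))
#' @export
linying_fit <- function(data, weights = NULL,
                        weight_placement = c("both", "events-only"),
                        tau = NULL) {
  weight_placement <- match.arg(weight_placement)
  prep <- fit_prep(data)
  w <- resolve_weights(data, weights)[prep$ord]
  tau <- tau %||% prep$tau
  sw_stopifnot_scalar_num(tau, "tau", positive = TRUE)

  eng <- ah_engine(prep, w, weight_placement, tau)
  n <- prep$n; p <- prep$p
  qr_A <- qr(eng$A)
  if (qr_A$rank < p) {
    sw_abort("singular covariate dispersion matrix (collinear covariates or no follow-up time)",
             "survweight_error_singular")
  }
  alpha <- drop(solve(qr_A, eng$b))
  A_inv <- solve(qr_A, diag(p))

  score <- eng$b - drop(eng$A %*% alpha)             # U1 (total) at alpha-hat

  # Lin-Ying natural (martingale, dN-based) covariance
  ia <- rep(seq_len(p), times = p); ib <- rep(seq_len(p), each = p)
  B0 <- matrix(colSums((w[eng$ev]^2) * eng$resid_ev[, ia, drop = FALSE] *
                         eng$resid_ev[, ib, drop = FALSE]), p, p)
  model_cov <- A_inv %*% B0 %*% A_inv

  U1i <- ah_influence(prep, w, eng, alpha)
  E_tot <- crossprod(U1i)
  sandwich_cov <- A_inv %*% E_tot %*% A_inv

  cn <- prep$covariates
  dimnames(model_cov) <- dimnames(sandwich_cov) <- list(cn, cn)
  structure(list(
    alpha_hat = stats::setNames(alpha, cn),
    score = stats::setNames(score, cn),
    score_norm = max(abs(score)),
    D_hat = eng$A / n,
    E_hat = E_tot / n,
    model_cov = model_cov,
    sandwich_cov = sandwich_cov,
    residuals = U1i,
    converged = TRUE, n_iter = 0L,
    n = n, n_events = length(eng$ev),
    weight_placement = weight_placement, tau = tau,
    data = data, w_used = w, prep = prep, eng = eng
  ), class = "survweight_ah")
}

# Per-subject estimating-function contributions (weighted martingale-residual
# integrals), rows in prep (time-sorted) order:
#   U1_i = w_i [ d_i (Z_i - zbar(X_i))
#                - sum_{event t <= X_i} (Z_i - zbar(t)) dNA(t)
#                - sum_{k: u_k <= X_i} delta_k (Z_i - zbar_k)(Z_i - zbar_k)' a ]
# with dNA(t) the weighted Nelson-Aalen increment sum_j w_j dN_j(t) / Sv0(t).
# Under the default placement sum_i U1_i = U1(alpha-hat) = 0 exactly.
ah_influence <- function(prep, w, eng, alpha) {
  n <- prep$n; p <- prep$p
  Z <- prep$Z

  # event-time quantities
  ev <- eng$ev
  dWev <- as.numeric(rowsum(w[ev], eng$ev_blk))
  ev_blocks <- sort(unique(eng$ev_blk))
  dNA <- dWev / eng$Sv0[ev_blocks]
  ev_times <- eng$u[ev_blocks]
  zbar_ev <- eng$zbar[ev_blocks, , drop = FALSE]

  cnt <- findInterval(prep$time, ev_times)
  cumNA <- c(0, cumsum(dNA))
  cumNAz <- rbind(rep(0, p), apply2_cumsum(dNA * zbar_ev))
  H <- cumNA[cnt + 1L]                                 # sum dNA up to X_i
  Gz <- cumNAz[cnt + 1L, , drop = FALSE]               # sum zbar dNA up to X_i
  term2 <- Z * H - Gz

  # drift term: cumulative over intervals with u_k <= X_i
  za <- drop(eng$zbar %*% alpha)                       # K
  d0 <- cumsum(eng$delta)                              # sum delta
  d1 <- apply2_cumsum(eng$delta * eng$zbar)            # sum delta zbar
  d1a <- cumsum(eng$delta * za)                        # sum delta zbar'a
  d2a <- apply2_cumsum(eng$delta * za * eng$zbar)      # sum delta zbar zbar'a
  kcnt <- prep$block_id                                # u_k <= X_i  <=>  k <= block(i)
  C0 <- d0[kcnt]; C1 <- d1[kcnt, , drop = FALSE]
  C1a <- d1a[kcnt]; C2a <- d2a[kcnt, , drop = FALSE]
  Za <- drop(Z %*% alpha)
  term3 <- (Za * C0) * Z - Z * C1a - Za * C1 + C2a

  evterm <- matrix(0, n, p)
  evterm[ev, ] <- eng$resid_ev
  w * (evterm - term2 - term3)
}

apply2_cumsum <- function(m) {
  m <- as.matrix(m)
  out <- apply(m, 2, cumsum)
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(m))
  out
}

#' Model-robust (sandwich) covariance of an additive-hazards fit
#'
#' Returns `D^-1 E D^-1 / n` built from the estimating-function slope matrix
#' (bread) and the outer products of per-subject weighted martingale-residual
#' integrals (meat); valid for the least-false parameter under
#' misspecification.
#'
#' @param fit A [linying_fit()] object.
#' @return A p x p covariance matrix for `alpha_hat`.
#' @export
additive_sandwich <- function(fit) {
  stopifnot(inherits(fit, "survweight_ah"))
  fit$sandwich_cov
}

#' Baseline cumulative hazard for the additive-hazards fit
#'
#' `L0(t) = sum_{event times s <= t} dW(s) / R(s) - int_0^t alpha' zbar(u) du`,
#' the weighted Nelson-Aalen estimator minus the fitted covariate drift; the
#' first term is a step function, the second piecewise linear.
#'
#' @param fit A [linying_fit()] object.
#' @return A tibble of class `survweight_baseline` with columns `time` and
#'   `cum_haz` evaluated at the distinct observed times; attribute `fun`
#'   evaluates the estimate at arbitrary times.
#' @export
linying_baseline <- function(fit) {
  stopifnot(inherits(fit, "survweight_ah"))
  prep <- fit$prep; eng <- fit$eng
  u <- eng$u
  K <- length(u)

  ev_blocks <- sort(unique(eng$ev_blk))
  dWev <- as.numeric(rowsum(fit$w_used[eng$ev], eng$ev_blk))
  if (any(eng$Sv0[ev_blocks] <= 0)) {
    sw_abort("zero at-risk sum at an event time", "survweight_error_input")
  }
  na_inc <- numeric(K)
  na_inc[ev_blocks] <- dWev / eng$Sv0[ev_blocks]
  na_cum <- cumsum(na_inc)

  za <- drop(eng$zbar %*% as.numeric(fit$alpha_hat))
  drift <- cumsum(eng$delta * za)

  ch <- na_cum - drift
  out <- tibble::tibble(time = u, cum_haz = ch)
  na_fun <- stats::stepfun(u, c(0, na_cum), right = FALSE)
  drift_fun <- stats::approxfun(c(0, u), c(0, drift), rule = 2)
  attr(out, "fun") <- function(t) na_fun(t) - drift_fun(t)
  class(out) <- c("survweight_baseline", class(out))
  out
}

#' @export
print.survweight_ah <- function(x, ...) {
  cat(sprintf(
    "<survweight_ah> n = %d, events = %d, placement = %s, tau = %g\n",
    x$n, x$n_events, x$weight_placement, x$tau))
  print(tidy(x))
  invisible(x)
}
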