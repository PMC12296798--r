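# Independent brute-force oracles and small-data generators used across the
# suite. These deliberately share no code with the package internals: risk
# sets are rebuilt by explicit subsetting and integrals by explicit loops.

# random small right-censored dataset (p = 1 unless p given)
rand_dataset <- function(n, p = 1, tie_prob = 0, wmin = 0.2, wmax = 2,
                         event_prob = 0.7) {
  tt <- rexp(n)
  if (tie_prob > 0) tt <- round(tt, 1) + 0.05
  ev <- rbinom(n, 1, event_prob)
  if (!any(ev == 1)) ev[sample(n, 1)] <- 1
  df <- data.frame(time = tt, event = ev)
  for (j in seq_len(p)) df[[paste0("z", j)]] <- rnorm(n)
  df$w <- runif(n, wmin, wmax)
  df
}

as_sd <- function(df, weights = df$w, covars = grep("^z", names(df), value = TRUE)) {
  surv_data(df, time, event, covariates = covars, weights = weights)
}

# weighted log partial likelihood (Breslow), evaluated on a beta grid,
# built from first principles by explicit risk-set subsetting
grid_cox_loglik <- function(beta_grid, time, event, z, w) {
  ll <- numeric(length(beta_grid))
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    # log S0(beta, X_i) over the whole grid at once
    s0 <- exp(outer(beta_grid, z[risk])) %*% w[risk]
    ll <- ll + w[i] * (beta_grid * z[i] - log(as.numeric(s0)))
  }
  ll
}

grid_cox_argmax <- function(time, event, z, w, lo = -5, hi = 5, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  grid[which.max(grid_cox_loglik(grid, time, event, z, w))]
}

# naive Breslow weighted score, explicit loops
naive_cox_score <- function(beta, time, event, zmat, w, placement = "both") {
  zmat <- as.matrix(zmat)
  r <- exp(drop(zmat %*% beta))
  rw <- if (placement == "both") w * r else r
  u <- rep(0, ncol(zmat))
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    s0 <- sum(rw[risk])
    s1 <- colSums(rw[risk] * zmat[risk, , drop = FALSE])
    u <- u + w[i] * (zmat[i, ] - s1 / s0)
  }
  u
}

# naive Lin-Ying estimating function U1(alpha), explicit interval loops
naive_U1 <- function(alpha, time, event, zmat, w, tau = max(time),
                     placement = "both") {
  zmat <- as.matrix(zmat)
  vw <- if (placement == "both") w else rep(1, length(w))
  u <- rep(0, ncol(zmat))
  uts <- sort(unique(time))
  for (tk in uts[uts <= tau]) {
    risk <- which(time >= tk)
    zb <- colSums(vw[risk] * zmat[risk, , drop = FALSE]) / sum(vw[risk])
    dn <- which(time == tk & event == 1)
    for (i in dn) u <- u + w[i] * (zmat[i, ] - zb)
  }
  prev <- 0
  for (tk in uts) {
    hi <- min(tk, tau)
    if (hi > prev) {
      risk <- which(time >= tk)
      zb <- colSums(vw[risk] * zmat[risk, , drop = FALSE]) / sum(vw[risk])
      for (i in risk) {
        u <- u - w[i] * (zmat[i, ] - zb) * sum(zmat[i, ] * alpha) * (hi - prev)
      }
    }
    prev <- hi
  }
  u
}

ly_bisection_root <- function(time, event, z, w, tau = max(time),
                              lo = -10, hi = 10) {
  uniroot(function(a) naive_U1(a, time, event, matrix(z, ncol = 1), w, tau),
          c(lo, hi), tol = 1e-12)$root
}

# Nelson-Aalen estimator from first principles
naive_nelson_aalen <- function(time, event, w = rep(1, length(time))) {
  ev_times <- sort(unique(time[event == 1]))
  inc <- vapply(ev_times, function(t) {
    sum(w[time == t & event == 1]) / sum(w[time >= t])
  }, numeric(1))
  data.frame(time = ev_times, cum_haz = cumsum(inc))
}
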