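test_that("cox_score matches the hand-evaluated two-subject example", {
  df <- data.frame(time = c(1, 2), event = c(1, 1), z = c(1, 0))
  sd <- surv_data(df, time, event, covariates = "z")
  # event 1: z = 1 minus risk-set mean 0.5; event 2: 0 - 0
  expect_equal(as.numeric(cox_score(0, sd, ties = "breslow")), 0.5)
})

test_that("cox_score is zero when all covariates are identical", {
  df <- data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 0, 1), z = rep(2, 4))
  sd <- surv_data(df, time, event, covariates = "z")
  for (b in c(-1, 0, 2)) {
    expect_equal(as.numeric(cox_score(b, sd)), 0)
  }
})

test_that("cox_score is homogeneous of degree one in the weights", {
  df <- data.frame(time = c(1, 2), event = c(1, 1), z = c(1, 0))
  sd <- surv_data(df, time, event, covariates = "z")
  s1 <- cox_score(0, sd, weights = c(1, 1), ties = "breslow")
  s2 <- cox_score(0, sd, weights = c(2, 2), ties = "breslow")
  expect_equal(as.numeric(s2), 2 * as.numeric(s1))
})

test_that("cox_score agrees with explicit risk-set loops on random data", {
  set.seed(11)
  for (rep in 1:10) {
    df <- rand_dataset(sample(4:12, 1), p = 2)
    sd <- as_sd(df)
    b <- rnorm(2, sd = 0.5)
    for (pl in c("both", "events-only")) {
      expect_equal(
        as.numeric(cox_score(b, sd, ties = "breslow", weight_placement = pl)),
        unname(naive_cox_score(b, df$time, df$event, df[, c("z1", "z2")],
                               df$w, pl)),
        tolerance = 1e-10)
    }
  }
})

test_that("cox_fit maximizes the weighted partial likelihood (grid oracle)", {
  set.seed(5)
  for (rep in 1:8) {
    df <- rand_dataset(sample(4:8, 1))
    sd <- as_sd(df)
    fit <- cox_fit(sd, ties = "breslow")
    gm <- grid_cox_argmax(df$time, df$event, df$z1, df$w)
    expect_lt(abs(as.numeric(fit$beta_hat) - gm), 1e-4)
    expect_true(fit$converged)
    expect_lte(fit$score_norm, fit$tol)
  }
})

test_that("integer weights equal row duplication under Breslow ties", {
  set.seed(23)
  df <- rand_dataset(6, event_prob = 0.8)
  k <- c(3, 1, 2, 1, 2, 2)
  sd_w <- as_sd(df, weights = k)
  dup <- df[rep(seq_len(6), k), ]
  sd_dup <- as_sd(dup, weights = rep(1, nrow(dup)))
  f1 <- cox_fit(sd_w, ties = "breslow")
  f2 <- cox_fit(sd_dup, ties = "breslow")
  expect_equal(as.numeric(f1$beta_hat), as.numeric(f2$beta_hat),
               tolerance = 1e-8)
  a1 <- linying_fit(sd_w)
  a2 <- linying_fit(sd_dup)
  expect_equal(as.numeric(a1$alpha_hat), as.numeric(a2$alpha_hat),
               tolerance = 1e-10)
})

test_that("weighted fit matches survival::coxph for both tie methods", {
  skip_if_not_installed("survival")
  set.seed(42)
  df <- rand_dataset(150, p = 2, tie_prob = 0.6)
  sd <- as_sd(df)
  for (tie in c("breslow", "efron")) {
    f <- cox_fit(sd, ties = tie)
    g <- survival::coxph(survival::Surv(time, event) ~ z1 + z2, data = df,
                         weights = df$w, ties = tie, robust = TRUE)
    expect_equal(as.numeric(f$beta_hat), as.numeric(coef(g)), tolerance = 1e-7)
    expect_equal(unname(f$model_cov), unname(g$naive.var), tolerance = 1e-7)
    expect_equal(unname(f$sandwich_cov), unname(g$var), tolerance = 1e-7)
  }
})

test_that("the weighted log partial likelihood is concave with the fit at its max", {
  set.seed(9)
  df <- rand_dataset(60)
  sd <- as_sd(df)
  f <- cox_fit(sd, ties = "breslow")
  grid <- seq(-3, 3, by = 0.01)
  ll <- grid_cox_loglik(grid, df$time, df$event, df$z1, df$w)
  # concavity: second differences non-positive
  expect_true(all(diff(ll, differences = 2) <= 1e-8))
  # the Newton solution dominates every grid point
  expect_gte(f$loglik, max(ll) - 1e-8)
})

test_that("collinear covariates raise a singular-information error", {
  df <- data.frame(time = rexp(30), event = rbinom(30, 1, 0.8), z1 = rnorm(30))
  df$z2 <- 2 * df$z1
  df$w <- 1
  sd <- as_sd(df)
  expect_error(cox_fit(sd), class = "survweight_error_singular")
})

test_that("complete separation is reported as non-convergence", {
  # covariate perfectly ordered with survival: monotone likelihood
  df <- data.frame(time = 1:20, event = rep(1, 20), z1 = sort(rnorm(20)),
                   w = 1)
  sd <- as_sd(df)
  expect_error(cox_fit(sd), class = "survweight_error_nonconvergence")
})

test_that("breslow_baseline reduces to Nelson-Aalen at beta = 0, w = 1", {
  set.seed(13)
  df <- rand_dataset(25, tie_prob = 0.4)
  df$z1 <- 0 * df$z1            # no covariate effect estimable -> beta-hat = 0
  df$z1[1] <- 1e-30             # keep dispersion nonzero but negligible
  sd <- as_sd(df, weights = rep(1, 25))
  f <- cox_fit(sd, ties = "breslow")
  bl <- breslow_baseline(f)
  na <- naive_nelson_aalen(df$time, df$event)
  expect_equal(bl$time, na$time)
  expect_equal(bl$cum_haz, na$cum_haz, tolerance = 1e-8)
})

test_that("breslow_baseline: single event gives mass 1 and weights cancel", {
  df <- data.frame(time = c(1, 2), event = c(1, 0), z = c(1, 0))
  sd <- surv_data(df, time, event, covariates = "z")
  f <- cox_fit(sd)
  bl <- breslow_baseline(f)
  # only subject 1 at risk... both at risk at t=1: L0(1) = 1/(r1+r2)
  expect_equal(bl$time, 1)
  expect_gt(bl$cum_haz, 0)

  f2 <- cox_fit(sd, weights = c(2, 2))
  expect_equal(breslow_baseline(f2)$cum_haz, bl$cum_haz, tolerance = 1e-8)
})

test_that("score residuals sum to zero at the optimum (both tie methods)", {
  set.seed(61)
  df <- rand_dataset(70, p = 2, tie_prob = 0.5)
  sd <- as_sd(df)
  for (tie in c("breslow", "efron")) {
    f <- cox_fit(sd, ties = tie)
    expect_lt(max(abs(colSums(f$residuals))), 1e-8)
    expect_true(isSymmetric(unname(f$sandwich_cov), tol = 1e-10))
    expect_true(all(diag(f$sandwich_cov) >= 0))
  }
})

test_that("events-only placement solves the displayed estimating equation", {
  set.seed(99)
  df <- rand_dataset(50)
  sd <- as_sd(df)
  f <- cox_fit(sd, ties = "breslow", weight_placement = "events-only")
  u <- naive_cox_score(as.numeric(f$beta_hat), df$time, df$event,
                       matrix(df$z1), df$w, placement = "events-only")
  expect_lt(max(abs(u)), 1e-8)
  # and it differs from the case-weight fit when weights are informative
  fb <- cox_fit(sd, ties = "breslow")
  expect_gt(abs(as.numeric(f$beta_hat) - as.numeric(fb$beta_hat)), 1e-6)
})
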