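test_that("ph simulation with null effect gives the baseline event-time law", {
  spec <- dgp_spec("ph", coef = 0, n = 10000)
  d <- simulate_survival(spec, seed = 1)
  # Exp(1) event times: mean 1, MC SE = 1/sqrt(n)
  expect_lt(abs(mean(d$time) - 1), 3 / sqrt(10000))
  expect_true(all(d$event == 1))
})

test_that("ah simulation produces the additive group hazards", {
  spec <- dgp_spec("ah", coef = 0.5,
                   baseline = list(type = "constant", rate = 1), n = 8000)
  d <- simulate_survival(spec, seed = 2)
  g1 <- d$time[d$z1 == 1]
  g0 <- d$time[d$z1 == 0]
  # group hazards 1.5 and 1.0: compare mean event times
  expect_lt(abs(mean(g1) - 1 / 1.5), 4 / (1.5 * sqrt(length(g1))))
  expect_lt(abs(mean(g0) - 1), 4 / sqrt(length(g0)))
  # Nelson-Aalen slope in group 1 near 1.5 over [0, 0.5]
  na <- naive_nelson_aalen(g1, rep(1, length(g1)))
  slope <- with(subset(na, time < 0.5), coef(lm(cum_haz ~ time))[2])
  expect_lt(abs(slope - 1.5), 0.1)
})

test_that("simulation is reproducible under a seed", {
  spec <- dgp_spec("ph", coef = c(0.3, -0.2), n = 50,
                   censoring = list(type = "uniform", max = 3))
  d1 <- simulate_survival(spec, seed = 7)
  d2 <- simulate_survival(spec, seed = 7)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
})

test_that("Kaplan-Meier of a null ph cohort tracks exp(-L0(t))", {
  skip_if_not_installed("survival")
  spec <- dgp_spec("ph", coef = 0,
                   baseline = list(type = "weibull", shape = 1.5, scale = 1),
                   censoring = list(type = "uniform", max = 3), n = 10000)
  d <- simulate_survival(spec, seed = 3)
  km <- survival::survfit(survival::Surv(time, event) ~ 1,
                          data = as.data.frame(d))
  for (t0 in c(0.25, 0.5, 1, 1.5)) {
    s_km <- summary(km, times = t0)$surv
    s_true <- exp(-(t0 / 1)^1.5)
    expect_lt(abs(s_km - s_true), 0.02)
  }
})

test_that("an additive spec allowing negative hazard is rejected at construction", {
  expect_error(
    dgp_spec("ah", coef = -2, baseline = list(type = "constant", rate = 1)),
    class = "survweight_error_invalid_dgp")
  # the same magnitude is fine when the support keeps the hazard positive
  expect_s3_class(
    dgp_spec("ah", coef = -0.8, baseline = list(type = "constant", rate = 1)),
    "survweight_dgp")
})

test_that("censoring calibration hits the target fraction within 2 points", {
  spec <- dgp_spec("ph", coef = 0.7,
                   censoring = list(type = "exponential", rate = 1), n = 10000)
  for (target in c(0.2, 0.5)) {
    sp <- calibrate_censoring(spec, target, n_mc = 50000, seed = 4)
    d <- simulate_survival(sp, n = 10000, seed = 5)
    expect_lt(abs(mean(d$event == 0) - target), 0.02)
  }
})

test_that("oracle-true predictions satisfy the survival/hazard identity and give constant weights under beta = 0", {
  spec <- dgp_spec("ph", coef = 0, n = 300,
                   censoring = list(type = "uniform", max = 3))
  d <- simulate_survival(spec, seed = 6)
  pr <- external_predictions(d, spec, builder = "oracle_true", horizon = 1)
  expect_equal(pr$surv_prob, exp(-pr$cum_haz))
  # beta = 0: same prediction for everyone -> weighted fit = unweighted fit
  expect_equal(length(unique(round(pr$surv_prob, 12))), 1L)
  spec2 <- dgp_spec("ph", coef = 0.8, n = 300,
                    censoring = list(type = "uniform", max = 3))
  d2 <- simulate_survival(spec2, seed = 6)
  w <- weights_from_survival_prob(pr$surv_prob, horizon = 1)
  f_w <- cox_fit(d2, weights = as.numeric(w) )
  f_u <- cox_fit(d2)
  expect_equal(as.numeric(f_w$beta_hat), as.numeric(f_u$beta_hat),
               tolerance = 1e-8)
})

test_that("external model fits satisfy S = exp(-H) on their own scale", {
  spec <- dgp_spec("ph", coef = c(0.7, -0.4), n = 400,
                   censoring = list(type = "exponential", rate = 0.3))
  d <- simulate_survival(spec, seed = 8)
  pr <- external_predictions(d, spec, builder = "ph_fit", horizon = 1,
                             external_n = 400, seed = 9)
  expect_equal(pr$surv_prob, exp(-pr$cum_haz), tolerance = 1e-12)
  pr2 <- external_predictions(d, spec, builder = "ah_fit", horizon = 1,
                              external_n = 400, seed = 9)
  expect_equal(pr2$surv_prob, exp(-pr2$cum_haz), tolerance = 1e-12)
})

test_that("omitting the strongest covariate decorrelates predictions from it", {
  spec <- dgp_spec("ph", coef = c(1.2, 0.3), n = 2000,
                   covariates = list(list(type = "truncnorm", mean = 0, sd = 1,
                                          lower = -2.5, upper = 2.5),
                                     list(type = "bernoulli", prob = 0.5)),
                   censoring = list(type = "exponential", rate = 0.3))
  d <- simulate_survival(spec, seed = 10)
  pr_full <- external_predictions(d, spec, builder = "ph_fit", horizon = 1,
                                  external_n = 2000, seed = 11)
  pr_sub <- external_predictions(d, spec, builder = "ph_fit", horizon = 1,
                                 covariate_subset = 2, external_n = 2000,
                                 seed = 11)
  z1 <- as.data.frame(d)$z1
  expect_gt(abs(cor(pr_full$surv_prob, z1)), 0.25)
  expect_lt(abs(cor(pr_sub$surv_prob, z1)), 0.15)
})

test_that("user_table predictions pass through on both scales", {
  spec <- dgp_spec("ph", coef = 0.5, n = 10)
  d <- simulate_survival(spec, seed = 12)
  tb <- data.frame(surv_prob = seq(0.1, 1, length.out = 10))
  pr <- external_predictions(d, spec, builder = "user_table", table = tb)
  expect_equal(pr$surv_prob, tb$surv_prob)
  expect_equal(pr$cum_haz, -log(tb$surv_prob))
})

test_that("least-false oracle recovers the truth under correct specification", {
  spec <- dgp_spec("ph", coef = 0.7, n = 500,
                   censoring = list(type = "exponential", rate = 0.25))
  o <- least_false_oracle(spec, weight_rule = "none", model = "cox",
                          n_oracle = 20000, seed = 13, blocks = 10)
  expect_lt(abs(as.numeric(o$estimate) - 0.7), 3 * as.numeric(o$mc_se))
  o_w <- least_false_oracle(spec, weight_rule = "survival_prob", model = "cox",
                            horizon = 1, n_oracle = 20000, seed = 13,
                            blocks = 10)
  # informative weights do not move the target under correct specification
  expect_lt(abs(as.numeric(o_w$estimate) - 0.7), 3 * as.numeric(o_w$mc_se))
})

test_that("misspecified-model oracle is self-consistent across scales", {
  # true ph fitted with the additive model: alpha* is not the ph coefficient,
  # but a large fit should land on the oracle value
  spec <- dgp_spec("ph", coef = 0.7, n = 4000,
                   censoring = list(type = "uniform", max = 3))
  o <- least_false_oracle(spec, weight_rule = "none", model = "additive",
                          n_oracle = 60000, seed = 14, blocks = 10)
  d <- simulate_survival(spec, n = 4000, seed = 15)
  a <- linying_fit(d)
  se_fit <- sqrt(diag(a$sandwich_cov))
  comb <- sqrt(se_fit^2 + as.numeric(o$mc_se)^2)
  expect_lt(abs(as.numeric(a$alpha_hat) - as.numeric(o$estimate)), 2.5 * comb)
})
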