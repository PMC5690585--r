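test_that("KM matches hand product-limit values", {
  # (5, event), (8, censored), (12, event): S(5) = 2/3; at t = 12 the
  # censored person has left the risk set, so S(12) = 2/3 * (1 - 1/1) = 0
  r <- fixture_records(time = c(5, 8, 12), event = c(1, 0, 1))
  km <- km_estimate(r, group = NULL)
  ev <- km[km$n_event > 0, ]
  expect_equal(ev$time, c(5, 12))
  expect_equal(ev$survival, oracle_km(c(5, 8, 12), c(1, 0, 1))$survival)
  expect_equal(ev$survival, c(2/3, 0))

  # all censored: flat at 1
  r <- fixture_records(time = c(3, 6, 9), event = c(0, 0, 0))
  km <- km_estimate(r, group = NULL)
  expect_true(all(km$survival == 1))

  # distinct events, n = 4: steps 3/4, 1/2, 1/4, 0
  r <- fixture_records(time = 1:4, event = rep(1, 4))
  km <- km_estimate(r, group = NULL)
  expect_equal(km$survival, c(0.75, 0.5, 0.25, 0))
})

test_that("KM agrees with the oracle on random censored samples", {
  set.seed(31)
  for (i in 1:5) {
    t <- ceiling(rexp(40, 0.1))
    e <- rbinom(40, 1, 0.6)
    r <- fixture_records(time = t, event = e)
    km <- km_estimate(r, group = NULL)
    orc <- oracle_km(t, e)
    got <- km[km$n_event > 0, c("time", "survival")]
    expect_equal(got$time, orc$time)
    expect_equal(got$survival, orc$survival)
  }
})

test_that("log-rank behaves under symmetry and matches the hand table", {
  # two identical groups: statistic 0
  t <- c(2, 4, 6, 8); e <- c(1, 1, 0, 1)
  r <- fixture_records(time = c(t, t), event = c(e, e),
                       group = rep(c("g1", "g2"), each = 4))
  lr <- logrank_test(r, group = "frailty_category")
  expect_equal(lr$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr$df, 1)
  expect_equal(lr$p_value, 1)

  # 4 groups -> df 3
  r4 <- fixture_records(time = rep(c(1, 2, 3, 4), 4), event = rep(1, 16),
                        group = rep(c("a", "b", "c", "d"), each = 4))
  expect_equal(logrank_test(r4, "frailty_category")$df, 3)

  # small 2-group fixture equals the O-E/V table
  set.seed(7)
  t2 <- ceiling(rexp(30, 0.2)) + runif(30) / 10  # no ties
  e2 <- rbinom(30, 1, 0.7)
  g2 <- rep(c("x", "y"), 15)
  r2 <- fixture_records(time = t2, event = e2, group = g2)
  expect_equal(logrank_test(r2, "frailty_category")$chi_square,
               oracle_logrank2(t2, e2, g2), tolerance = 1e-9)

  # invariant to group relabeling
  g2b <- ifelse(g2 == "x", "y", "x")
  r2b <- fixture_records(time = t2, event = e2, group = g2b)
  expect_equal(logrank_test(r2, "frailty_category")$chi_square,
               logrank_test(r2b, "frailty_category")$chi_square)

  expect_error(logrank_test(fixture_records(1:3, c(1, 1, 1))), "2 non-empty",
               class = "mfi_data_error")
})

test_that("Cox fit maximizes the Breslow partial likelihood", {
  set.seed(11)
  n <- 60
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.05 * exp(0.9 * x)) + seq(0.001, 0.06, length.out = n) # no ties
  e <- rbinom(n, 1, 0.8)
  r <- fixture_records(time = t, event = e,
                       group = ifelse(x == 1, "mild", "fit"))
  fit <- cox_fit(r, covariates = "frailty_category")
  beta_hat <- tidy(fit)$estimate[1]
  beta_oracle <- oracle_cox_binary(t, e, x)
  expect_lt(abs(beta_hat - beta_oracle), 1e-6)
  expect_true(fit$converged)

  td <- tidy(fit)
  expect_equal(td$hazard_ratio, exp(td$estimate))
  expect_equal(td$conf_low, exp(td$estimate - qnorm(0.975) * td$std_error))
  expect_equal(td$conf_high, exp(td$estimate + qnorm(0.975) * td$std_error))
  expect_true(all(td$conf_low < td$hazard_ratio & td$hazard_ratio < td$conf_high))

  g <- glance(fit)
  expect_equal(g$n, n)
  expect_equal(g$n_event, sum(e))
  expect_true(g$converged)
})

test_that("the score test at beta=0 equals the two-group log-rank statistic", {
  set.seed(13)
  n <- 50
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.05 * exp(0.7 * x)) + seq(0.001, 0.05, length.out = n)
  e <- rbinom(n, 1, 0.75)
  r <- fixture_records(time = t, event = e,
                       group = ifelse(x == 1, "mild", "fit"))
  sc <- glance(cox_fit(r, covariates = "frailty_category"))$score_statistic
  lr <- logrank_test(r, "frailty_category")$chi_square
  expect_equal(sc, lr, tolerance = 1e-8)
})

test_that("a covariate independent of the outcome gives HR near 1", {
  set.seed(17)
  n <- 4000
  t <- rexp(n, 0.1)
  e <- rbinom(n, 1, 0.8)
  r <- fixture_records(time = t, event = e,
                       group = sample(c("fit", "mild"), n, replace = TRUE))
  td <- tidy(cox_fit(r, covariates = "frailty_category"))
  expect_true(td$conf_low[1] < 1 & 1 < td$conf_high[1])
  expect_lt(abs(td$hazard_ratio[1] - 1), 0.15)
})

test_that("complete separation is flagged as non-converged", {
  # the 'mild' group has all events far earlier than any 'fit' event:
  # monotone likelihood
  t <- c(1:10, 101:110)
  e <- rep(1, 20)
  r <- fixture_records(time = t, event = e,
                       group = rep(c("mild", "fit"), each = 10))
  fit <- suppressWarnings(cox_fit(r, covariates = "frailty_category"))
  expect_false(fit$converged)
})

test_that("no events is an error", {
  r <- fixture_records(time = 1:5, event = rep(0, 5))
  expect_error(cox_fit(r), "No events", class = "mfi_data_error")
})

test_that("discrimination matches the Mann-Whitney concordance oracle", {
  # small fixture with a 3-level predictor and ties in fitted values
  y <- c(1, 1, 1, 0, 0, 0, 0, 1, 0, 1)
  grp <- c("severe", "severe", "mild", "mild", "fit", "fit", "fit", "fit",
           "mild", "mild")
  r <- fixture_records(time = ifelse(y == 1, 50, 400), event = y,
                       group = grp, horizon = 365)
  attr(r, "horizon_days") <- 365
  d <- discrimination(r)
  m <- glm(y ~ factor(grp), family = binomial())
  expect_equal(d$c_statistic, oracle_concordance(fitted(m), y))
  expect_gte(d$pseudo_r2_nagelkerke, d$pseudo_r2_cox_snell)
  expect_equal(d$n, 10)

  # perfectly separating predictor: C = 1
  r2 <- fixture_records(time = c(10, 20, 400, 400), event = c(1, 1, 0, 0),
                        group = c("severe", "severe", "fit", "fit"),
                        horizon = 365)
  expect_equal(suppressWarnings(discrimination(r2))$c_statistic, 1.0)

  # predictor independent of outcome: C near 0.5
  set.seed(23)
  n <- 2000
  yy <- rbinom(n, 1, 0.3)
  rr <- fixture_records(time = ifelse(yy == 1, 100, 400), event = yy,
                        group = sample(c("fit", "mild", "moderate", "severe"),
                                       n, replace = TRUE),
                        horizon = 365)
  expect_lt(abs(discrimination(rr)$c_statistic - 0.5), 0.05)

  # all outcomes identical: undefined, flagged
  r3 <- fixture_records(time = rep(400, 4), event = rep(0, 4), horizon = 365)
  expect_warning(d3 <- discrimination(r3), "identical")
  expect_true(is.na(d3$c_statistic))
})

test_that("pre-horizon non-death censorings are excluded from discrimination", {
  r <- fixture_records(time = c(50, 100, 365, 365, 365), event = c(1, 0, 0, 0, 0),
                       group = c("severe", "mild", "fit", "fit", "mild"),
                       horizon = 365)
  r$status_reason <- c("event", "coverage", "horizon", "horizon", "horizon")
  d <- suppressWarnings(discrimination(r))
  expect_equal(d$n_excluded, 1)
  expect_equal(d$n, 4)
  # death-censored before horizon stays in as a control for non-fatal outcomes
  r$status_reason[2] <- "death"
  d2 <- suppressWarnings(discrimination(r))
  expect_equal(d2$n_excluded, 0)
  expect_equal(d2$n, 5)
})
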