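test_that("maximum likelihood recovers generating parameters", {
  d <- simulate_cohort(recovery_scenario(2000), seed = 21)
  fit <- curefrail(fit_formula, data = d,
                   control = curefrail_control(seed = 1, n_starts = 3))
  expect_true(fit$converged)
  z <- abs(coef(fit) - recovery_truth()) / fit$se
  expect_true(all(z < 3))
  # the gradient at the reported optimum is numerically zero
  fr <- fit$frame
  g <- numDeriv::grad(function(v) curefrail:::frame_loglik(v, fr, TRUE),
                      coef(fit))
  expect_lt(sqrt(sum(g^2)), 1e-4)
})

test_that("data generated without frailty yields a large theta estimate", {
  sc <- cure_scenario(
    n = 2000, margins = list(x = c(a = 0.5, b = 0.5)),
    params = cure_params(b0 = -0.8, b = c(xb = 0.6), beta = c(xb = 0.5),
                         shape = 1.2, scale = 0.05, theta = 1e9),
    censor_rate = 0.01, horizon = 120)
  d <- simulate_cohort(sc, seed = 31)
  fit <- curefrail(fit_formula, data = d,
                   control = curefrail_control(seed = 1, n_starts = 3))
  # 1/theta (the frailty variance) is near zero
  expect_lt(1 / fit$params$theta, 0.2)
  truth <- recovery_truth()[1:5]
  z <- abs(coef(fit)[1:5] - truth) / fit$se[1:5]
  expect_true(all(z < 3))
})

test_that("degenerate censoring patterns are refused", {
  d <- data.frame(time = 1:10 + 0.5, event = 1, x = rep(c("a", "b"), 5))
  expect_error(curefrail(fit_formula, data = d), "unidentifiable")
  d$event <- 0
  expect_error(curefrail(fit_formula, data = d), "censored")
})

test_that("Wald intervals reproduce hand arithmetic and stay in support", {
  fake <- structure(list(
    estimate = c(x = 0.54), se = c(x = 0.23),
    vcov = matrix(0.23^2, 1, 1, dimnames = list("x", "x"))),
    class = "curefrail")
  ci <- confint(fake, level = 0.95)
  expect_equal(unname(ci[1, c("lower", "upper")]),
               0.54 + c(-1, 1) * qnorm(0.975) * 0.23, tolerance = 1e-10)
  # zero SE collapses to the point estimate
  fake$se[] <- 0
  ci0 <- confint(fake)
  expect_equal(unname(ci0[1, "lower"]), unname(ci0[1, "upper"]))

  d <- simulate_cohort(recovery_scenario(500), seed = 22)
  fit <- curefrail(fit_formula, data = d,
                   control = curefrail_control(seed = 1, n_starts = 2))
  ci <- confint(fit)
  expect_true(all(ci[c("shape", "scale", "theta"), ] > 0))
  expect_true(all(ci[, "lower"] < ci[, "upper"]))
})

test_that("estimates are invariant to record order and dummy relabeling", {
  d <- simulate_cohort(recovery_scenario(800), seed = 23)
  ctl <- curefrail_control(seed = 1, n_starts = 1)
  f1 <- curefrail(fit_formula, data = d, control = ctl)
  set.seed(99); d2 <- d[sample(nrow(d)), ]
  f2 <- curefrail(fit_formula, data = d2, control = ctl)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-4)
  # swapping the reference level flips the coefficient and shifts intercepts
  d3 <- d; d3$x <- stats::relevel(factor(d3$x), "b")
  f3 <- curefrail(survival::Surv(time, event) ~ x, data = d3, control = ctl)
  expect_equal(unname(coef(f3)["cure_xa"]), -unname(coef(f1)["cure_xb"]),
               tolerance = 1e-3)
  expect_equal(unname(coef(f3)["cure_(Intercept)"]),
               unname(coef(f1)["cure_(Intercept)"] + coef(f1)["cure_xb"]),
               tolerance = 1e-3)
})

test_that("estimator error shrinks with sample size", {
  truth <- recovery_truth()
  rmse_at <- function(n, seeds) {
    err <- sapply(seeds, function(s) {
      d <- simulate_cohort(recovery_scenario(n), seed = s)
      fit <- curefrail(fit_formula, data = d,
                       control = curefrail_control(seed = 1, n_starts = 1))
      coef(fit) - truth
    })
    sqrt(rowMeans(err^2))
  }
  small <- rmse_at(300, 1:12)
  large <- rmse_at(3000, 1:12)
  expect_true(all(large < small))
})
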