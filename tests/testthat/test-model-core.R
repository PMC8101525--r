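test_that("Weibull baseline hazard pieces behave as defined", {
  expect_equal(weibull_cumhaz(0, shape = 1.01, scale = 2.2), 0)
  expect_equal(weibull_cumhaz(1, shape = 0.7, scale = 3.3), 3.3)
  expect_equal(weibull_cumhaz(1, shape = 4.2, scale = 3.3), 3.3)
  expect_equal(weibull_cumhaz(2, shape = 2, scale = 0.5), 2)
  t <- seq(0, 50, by = 0.5)
  expect_true(all(diff(weibull_cumhaz(t, 1.7, 0.2)) >= 0))
  expect_error(weibull_cumhaz(-1, 1, 1), "non-negative")
  expect_error(weibull_cumhaz(1, 0, 1), "positive")
  expect_error(weibull_cumhaz(1, 1, -2), "positive")
})

test_that("logistic cure probability matches the link and its limits", {
  expect_equal(cure_probability(c(0, 0), b0 = 0, b = c(2, -3)), 0.5)
  expect_equal(cure_probability(1, b0 = 0, b = log(3)), 0.75)
  expect_gt(cure_probability(c(0, 0), b0 = 30, b = c(1, 1)), 1 - 1e-10)
  b0s <- seq(-3, 3, by = 0.5)
  p <- vapply(b0s, function(b0) cure_probability(c(1, 2), b0, c(0.3, -0.2)),
              numeric(1))
  expect_true(all(diff(p) > 0))
  expect_error(cure_probability(c(1, 2, 3), b0 = 0, b = c(1, 2)), "match")
})

test_that("frailty-marginal latency survival matches quadrature and limits", {
  p <- cure_params(b0 = 0, beta = c(x = 0.4), shape = 1.3, scale = 0.08,
                   theta = 2)
  for (t in c(0.5, 2, 5, 20)) {
    expect_equal(latency_survival(t, 1, p),
                 quad_latency_survival(t, 0.4, 1.3, 0.08, 2),
                 tolerance = 1e-8)
  }
  # no-frailty limit
  p_inf <- cure_params(b0 = 0, shape = 1, scale = 0.1, theta = 1e6)
  expect_equal(latency_survival(5, numeric(0), p_inf), exp(-0.5),
               tolerance = 1e-4)
  p0 <- cure_params(b0 = 0, shape = 1.3, scale = 0.08, theta = 0.7)
  expect_equal(latency_survival(0, numeric(0), p0), 1)
  s <- latency_survival(seq(0, 80, by = 1), numeric(0), p0)
  expect_true(all(diff(s) <= 0))
})

test_that("latency density is the negative derivative and integrates to one", {
  p <- cure_params(b0 = 0, beta = c(x = -0.3), shape = 1.6, scale = 0.03,
                   theta = 1.5)
  d_num <- -numDeriv::grad(function(t) latency_survival(t, 1, p), 3)
  expect_equal(latency_density(3, 1, p), d_num, tolerance = 1e-6)
  set.seed(11)
  for (i in 1:3) {
    pi <- cure_params(b0 = 0, shape = runif(1, 0.6, 2.5),
                      scale = runif(1, 0.01, 0.5), theta = runif(1, 0.5, 5))
    total <- integrate(function(t) latency_density(t, numeric(0), pi),
                       0, Inf, rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
  # exponential limit: shape 1, no frailty
  pe <- cure_params(b0 = 0, shape = 1, scale = 0.2, theta = Inf)
  expect_equal(latency_density(c(1, 5, 10), numeric(0), pe),
               0.2 * exp(-0.2 * c(1, 5, 10)))
  expect_error(latency_density(0, numeric(0), pe), "positive")
})

test_that("population survival mixes the plateau and the latency part", {
  p <- cure_params(b0 = qlogis(0.3), beta = numeric(0), shape = 1.2,
                   scale = 0.05, theta = 2)
  expect_equal(population_survival(0, numeric(0), numeric(0), p), 1)
  expect_equal(population_survival(1e9, numeric(0), numeric(0), p), 0.3,
               tolerance = 1e-5)
  # S_u(t*) = 0.5  =>  S_pop = 0.3 + 0.7 * 0.5 = 0.65
  tstar <- uniroot(function(t) latency_survival(t, numeric(0), p) - 0.5,
                   c(0.01, 500))$root
  expect_equal(population_survival(tstar, numeric(0), numeric(0), p), 0.65,
               tolerance = 1e-6)
  ts <- seq(0, 300, by = 3)
  sp <- population_survival(ts, matrix(0, length(ts), 0),
                            matrix(0, length(ts), 0), p)
  expect_true(all(sp >= 0.3 - 1e-12 & sp <= 1))
})

test_that("log-likelihood matches the hand-computed toy and is additive", {
  d <- toy_data()
  expect_equal(cure_loglik(toy_params(), d$time, d$event), toy_loglik_hand(),
               tolerance = 1e-10)
  expect_equal(cure_loglik(toy_params(1e9), d$time, d$event),
               toy_loglik_hand(), tolerance = 1e-6)
  # additivity under duplication, invariance under permutation
  set.seed(5)
  n <- 40
  dd <- data.frame(time = rexp(n, 0.1) + 0.01,
                   event = rbinom(n, 1, 0.6),
                   x = rnorm(n))
  p <- cure_params(b0 = -0.5, b = c(x = 0.3), beta = c(x = 0.4),
                   shape = 1.1, scale = 0.08, theta = 2)
  X <- matrix(dd$x, ncol = 1)
  ll1 <- cure_loglik(p, dd$time, dd$event, X, X)
  expect_equal(cure_loglik(p, rep(dd$time, 2), rep(dd$event, 2),
                           rbind(X, X), rbind(X, X)), 2 * ll1)
  o <- sample(n)
  expect_equal(cure_loglik(p, dd$time[o], dd$event[o],
                           X[o, , drop = FALSE], X[o, , drop = FALSE]), ll1)
  expect_error(cure_loglik(p, c(0, 1), c(1, 0)), "time 0")
  expect_error(cure_loglik(p, dd$time, dd$event, X[, c(1, 1)], X), "match")
})
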