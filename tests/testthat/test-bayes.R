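test_that("sampling the prior alone recovers its mean and SD", {
  lp <- function(v) sum(dnorm(v, 0, c(1, 3), log = TRUE))
  ch <- mh_sample(lp, init = c(0, 0), n_iter = 25000, burn_in = 5000,
                  thin = 1, seed = 12)
  dg <- suppressWarnings(mcmc_diagnostics(ch))
  m <- colMeans(ch$draws); s <- apply(ch$draws, 2, sd)
  mcse_mean <- s / sqrt(dg$ess)
  expect_true(all(abs(m - 0) < 3 * mcse_mean))
  # SD of a normal: MC error of the SD is roughly sd/sqrt(2 ess)
  expect_true(all(abs(s - c(1, 3)) < 3 * c(1, 3) / sqrt(2 * dg$ess)))
  expect_gt(ch$acceptance_rate, 0.15)
  expect_lt(ch$acceptance_rate, 0.55)
})

test_that("identical seeds give identical chains and IO round-trips", {
  lp <- function(v) -0.5 * sum(v^2)
  a <- mh_sample(lp, c(1, -1), n_iter = 2000, burn_in = 500, thin = 2,
                 seed = 3)
  b <- mh_sample(lp, c(1, -1), n_iter = 2000, burn_in = 500, thin = 2,
                 seed = 3)
  expect_identical(a$draws, b$draws)
  colnames(a$draws) <- c("p1", "p2")
  path <- file.path(tempdir(), "chain.csv")
  write_chain(a, path)
  back <- read_chain(path)
  expect_equal(back$draws, a$draws)
  expect_equal(back$seed, a$seed)
  expect_equal(back$proposal_sd, a$proposal_sd)
  expect_error(mh_sample(lp, c(0, 0), proposal_sd = 0), "positive")
  expect_error(mh_sample(lp, c(0, 0), n_iter = 100, burn_in = 100), "exceed")
  expect_error(mh_sample(function(v) -Inf, c(0, 0)), "finite")
})

test_that("posterior summaries follow their definitions", {
  const <- structure(list(draws = matrix(2.5, 200, 1,
                                         dimnames = list(NULL, "a")),
                          acceptance_rate = 0, burn_in = 0, thin = 1,
                          n_iter = 200, seed = 1, proposal_sd = 1),
                     class = "posterior_chain")
  s <- posterior_summary(const)
  expect_equal(s$sd, 0)
  expect_equal(s$lower, 2.5)
  expect_equal(s$upper, 2.5)
  s2 <- posterior_summary(matrix(1:100, 100, 1, dimnames = list(NULL, "a")))
  expect_equal(s2$mean, 50.5)
  expect_error(posterior_summary(matrix(1:50, 50, 1)), "short")
  # thinning an exchangeable chain leaves the summary unchanged (within MC error)
  set.seed(2)
  x <- matrix(rnorm(4000), ncol = 1, dimnames = list(NULL, "a"))
  expect_equal(posterior_summary(x)$mean,
               posterior_summary(x[seq(1, 4000, by = 4), , drop = FALSE])$mean,
               tolerance = 0.1)
})

test_that("diagnostics flag stuck chains and measure iid draws correctly", {
  set.seed(6)
  mk <- function() structure(list(
    draws = matrix(rnorm(4000), 2000, 2, dimnames = list(NULL, c("a", "b"))),
    acceptance_rate = 0.3, burn_in = 0, thin = 1, n_iter = 2000, seed = 1,
    proposal_sd = 1), class = "posterior_chain")
  chains <- list(mk(), mk())
  dg <- mcmc_diagnostics(chains)
  expect_true(all(abs(dg$rhat - 1) < 0.02))
  expect_true(all(abs(dg$ess - 4000) / 4000 < 0.2))
  stuck <- mk(); stuck$acceptance_rate <- 0
  stuck$draws[] <- 1
  expect_warning(mcmc_diagnostics(list(stuck)), "accepted no")
  if (requireNamespace("coda", quietly = TRUE)) {
    ess_coda <- coda::effectiveSize(coda::mcmc(chains[[1]]$draws))
    ess_ours <- suppressWarnings(mcmc_diagnostics(chains[[1]]))$ess
    expect_equal(unname(ess_ours), unname(ess_coda), tolerance = 0.25)
  }
})

test_that("the cure-model log-posterior is likelihood plus prior", {
  d <- toy_data()
  p <- toy_params()
  pr <- curefrail_prior(coef_sd = 10, log_sd = 10)
  hand <- toy_loglik_hand() +
    dnorm(0, 0, 10, log = TRUE) + # b0 = 0
    dnorm(log(1), 0, 10, log = TRUE) + dnorm(log(0.5), 0, 10, log = TRUE)
  expect_equal(cure_log_posterior(p, d$time, d$event, prior = pr), hand,
               tolerance = 1e-10)
  # priors-only target equals the log prior
  expect_equal(cure_log_posterior(p, NULL, prior = pr), hand - toy_loglik_hand())
  # flat-prior limit: posterior differences equal likelihood differences
  pr_flat <- curefrail_prior(coef_sd = 1e8, log_sd = 1e8)
  p2 <- toy_params(); p2$b0 <- 1
  dpost <- cure_log_posterior(p2, d$time, d$event, prior = pr_flat) -
    cure_log_posterior(p, d$time, d$event, prior = pr_flat)
  dll <- cure_loglik(p2, d$time, d$event) - cure_loglik(p, d$time, d$event)
  expect_equal(dpost, dll, tolerance = 1e-6)
})

test_that("the Bayesian fit summarizes, persists and stays in support", {
  d <- simulate_cohort(recovery_scenario(400), seed = 33)
  fit <- curefrail(fit_formula, data = d, method = "bayes",
                   control = curefrail_control(seed = 2, n_iter = 4000,
                                               burn_in = 1500, thin = 2,
                                               n_chains = 2))
  s <- summary(fit)
  expect_true(all(s$table[c("shape", "scale", "theta"), "lower"] > 0))
  expect_true(all(s$table$lower < s$table$upper))
  expect_equal(nrow(fit$draws),
               2 * floor((4000 - 1500) / 2))
  # reproducible end to end
  fit2 <- curefrail(fit_formula, data = d, method = "bayes",
                    control = curefrail_control(seed = 2, n_iter = 4000,
                                                burn_in = 1500, thin = 2,
                                                n_chains = 2))
  expect_identical(fit$draws, fit2$draws)
})
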