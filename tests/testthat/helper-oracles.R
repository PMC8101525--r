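# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# brute-force product-limit estimator: risk set counted by >=, so events at a
# tied time are removed after contributing (events before censorings)
brute_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  list(times = ts, surv = surv)
}

# frailty-marginal latency survival by adaptive quadrature against the
# Gamma(theta, theta) frailty density
quad_latency_survival <- function(t, eta, shape, scale, theta) {
  H <- scale * t^shape * exp(eta)
  # substitute u = F(w) (gamma CDF) so the integrand is bounded and smooth
  stats::integrate(function(u)
    exp(-stats::qgamma(u, theta, rate = theta) * H),
    0, 1, rel.tol = 1e-10, abs.tol = 1e-13)$value
}

# the two-record toy dataset: one event at t = 1, one censored at t = 2,
# no covariates, shape 1, scale 0.5, no frailty, cure probability 0.5
toy_data <- function() data.frame(time = c(1, 2), event = c(1, 0))

toy_params <- function(theta = Inf)
  cure_params(b0 = 0, shape = 1, scale = 0.5, theta = theta)

# hand computation of the toy log-likelihood (no frailty):
# event:    log[(1 - pi) * h0(1) exp(-H0(1))] = log(0.5 * 0.5 * exp(-0.5))
# censored: log[pi + (1 - pi) * exp(-H0(2))] = log(0.5 + 0.5 * exp(-1))
toy_loglik_hand <- function()
  log(0.5 * 0.5 * exp(-0.5)) + log(0.5 + 0.5 * exp(-1))

# single-binary-covariate recovery scenario (moderate cure fraction,
# exponential + administrative censoring)
recovery_scenario <- function(n) {
  cure_scenario(
    n = n,
    margins = list(x = c(a = 0.5, b = 0.5)),
    params = cure_params(b0 = -0.8, b = c(xb = 0.6), beta = c(xb = 0.5),
                         shape = 1.2, scale = 0.05, theta = 2),
    censor_rate = 0.01, horizon = 120)
}

recovery_truth <- function() {
  c("cure_(Intercept)" = -0.8, cure_xb = 0.6, surv_xb = 0.5,
    "log(shape)" = log(1.2), "log(scale)" = log(0.05), "log(theta)" = log(2))
}

fit_formula <- survival::Surv(time, event) ~ x

gastric_formula <-
  survival::Surv(time, event) ~ chemotherapy + morphology + metastasis

gastric_truth <- function() {
  p <- gastric_scenario()$params
  c("cure_(Intercept)" = unname(p$b0),
    stats::setNames(p$b, paste0("cure_", names(p$b))),
    stats::setNames(p$beta, paste0("surv_", names(p$beta))),
    "log(shape)" = log(p$shape), "log(scale)" = log(p$scale),
    "log(theta)" = log(p$theta))
}
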