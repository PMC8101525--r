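#' Weibull baseline cumulative hazard
#'
#' Baseline cumulative hazard of the latency (short-term survivor) component,
#' parameterised as \eqn{H_0(t) = \mathrm{scale} \cdot t^{\mathrm{shape}}}.
#'
#' @param t Vector of non-negative times (months).
#' @param shape Positive Weibull shape.
#' @param scale Positive Weibull scale (on the cumulative-hazard scale, i.e.
#'   the value of \eqn{H_0(1)}).
#' @return Numeric vector of cumulative hazards, zero at `t = 0` and
#'   nondecreasing in `t`.
#' @examples
#' weibull_cumhaz(c(0, 1, 2), shape = 2, scale = 0.5)
#' @export
weibull_cumhaz <- function(t, shape, scale) {
  check_positive(shape, "shape")
  check_positive(scale, "scale")
  if (any(!is.finite(t)) || any(t < 0))
    stop("'t' must be finite and non-negative", call. = FALSE)
  scale * t^shape
}

#' Weibull baseline hazard
#'
#' Instantaneous baseline hazard \eqn{h_0(t) = \mathrm{shape} \cdot
#' \mathrm{scale} \cdot t^{\mathrm{shape} - 1}} matching [weibull_cumhaz()].
#'
#' @inheritParams weibull_cumhaz
#' @return Numeric vector of hazards.
#' @export
weibull_hazard <- function(t, shape, scale) {
  check_positive(shape, "shape")
  check_positive(scale, "scale")
  if (any(!is.finite(t)) || any(t < 0))
    stop("'t' must be finite and non-negative", call. = FALSE)
  shape * scale * t^(shape - 1)
}

#' Cure probability under the logistic incidence model
#'
#' Probability of belonging to the cured (long-term survivor) subpopulation,
#' \eqn{\pi(x) = \mathrm{logit}^{-1}(b_0 + x'b)}. The logistic link makes
#' "odds of being cured" exact: each incidence coefficient exponentiates to an
#' odds ratio for cure.
#'
#' @param x Covariate vector, or matrix with one row per subject.
#' @param b0 Incidence intercept.
#' @param b Incidence coefficient vector (may have length zero).
#' @return Cure probabilities in (0, 1), one per subject.
#' @examples
#' cure_probability(c(0, 0), b0 = 0, b = c(1, -1)) # 0.5
#' cure_probability(1, b0 = 0, b = log(3))         # 0.75
#' @export
cure_probability <- function(x, b0, b) {
  if (is.null(dim(x))) x <- matrix(x, nrow = if (length(b) == 0L) length(x) else 1L)
  if (ncol(x) != length(b))
    stop("covariate dimension (", ncol(x), ") does not match length(b) (",
         length(b), ")", call. = FALSE)
  eta <- b0 + if (length(b)) drop(x %*% b) else rep(0, nrow(x))
  stats::plogis(eta)
}

#' Parameter set of the mixture cure rate frailty model
#'
#' Bundles the incidence intercept and coefficients (`b0`, `b`), the latency
#' proportional-hazards coefficients (`beta`), the Weibull baseline `shape`
#' and `scale`, and the gamma frailty shape `theta`. The frailty is
#' Gamma(theta, theta): mean one, variance `1/theta`; `theta = Inf` gives the
#' frailty-free Weibull mixture cure model.
#'
#' @param b0 Incidence intercept.
#' @param b Incidence coefficients (default none).
#' @param beta Latency coefficients (default none).
#' @param shape,scale Positive Weibull baseline parameters, see
#'   [weibull_cumhaz()].
#' @param theta Positive gamma frailty shape; `Inf` switches the frailty off.
#' @return An object of class `"cure_params"`.
#' @export
cure_params <- function(b0, b = numeric(0), beta = numeric(0),
                        shape, scale, theta = Inf) {
  check_positive(shape, "shape")
  check_positive(scale, "scale")
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) || theta <= 0)
    stop("'theta' must be a positive scalar (possibly Inf)", call. = FALSE)
  stopifnot(is.numeric(b0), length(b0) == 1L, is.numeric(b), is.numeric(beta))
  structure(list(b0 = b0, b = b, beta = beta,
                 shape = shape, scale = scale, theta = theta),
            class = "cure_params")
}

#' @export
print.cure_params <- function(x, digits = 4, ...) {
  cat("Mixture cure rate frailty model parameters\n")
  cat("  incidence : b0 =", format(x$b0, digits = digits))
  if (length(x$b)) cat(", b =", paste(format(x$b, digits = digits), collapse = ", "))
  cat("\n  latency   :")
  if (length(x$beta))
    cat(" beta =", paste(format(x$beta, digits = digits), collapse = ", "))
  else cat(" (no covariates)")
  cat("\n  baseline  : Weibull shape =", format(x$shape, digits = digits),
      ", scale =", format(x$scale, digits = digits), "\n")
  cat("  frailty   : Gamma(theta, theta), theta =",
      format(x$theta, digits = digits),
      if (is.finite(x$theta)) paste0("(variance ", format(1 / x$theta, digits = digits), ")")
      else "(no frailty)", "\n")
  invisible(x)
}

# linear predictor helper: X may be NULL/0-col for an empty coefficient set
lin_pred <- function(X, coefs, n) {
  if (length(coefs) == 0L) return(rep(0, n))
  if (is.null(dim(X))) X <- matrix(X, ncol = length(coefs))
  if (ncol(X) != length(coefs))
    stop("covariate dimension (", ncol(X), ") does not match coefficient length (",
         length(coefs), ")", call. = FALSE)
  drop(X %*% coefs)
}

#' Marginal survival of the uncured (latency component)
#'
#' Survival function of the time to event among uncured subjects with the
#' gamma frailty integrated out:
#' \deqn{S_u(t \mid x) = \left(1 + H_0(t) e^{x'\beta} / \theta\right)^{-\theta}.}
#' As \eqn{\theta \to \infty} this converges to the frailty-free
#' \eqn{\exp(-H_0(t) e^{x'\beta})}.
#'
#' @param t Vector of non-negative times.
#' @param x Latency covariate vector (or matrix, rows matching `t` or a
#'   single row recycled).
#' @param params A [cure_params()] object.
#' @return Survival probabilities in (0, 1], `1` at `t = 0`.
#' @export
latency_survival <- function(t, x, params) {
  if (any(!is.finite(t)) || any(t < 0))
    stop("'t' must be finite and non-negative", call. = FALSE)
  eta <- lin_pred(x, params$beta, length(t))
  H <- weibull_cumhaz(t, params$shape, params$scale) * exp(eta)
  if (is.finite(params$theta)) {
    exp(-params$theta * log1p(H / params$theta))
  } else {
    exp(-H)
  }
}

#' Marginal event-time density of the uncured
#'
#' Closed-form density \eqn{f_u(t \mid x) = -dS_u/dt =
#' h_0(t) e^{x'\beta} (1 + H_0(t) e^{x'\beta}/\theta)^{-\theta - 1}} of the
#' frailty-marginal latency distribution; integrates to one on \eqn{(0,\infty)}.
#'
#' @inheritParams latency_survival
#' @param t Vector of strictly positive times.
#' @return Densities (non-negative).
#' @export
latency_density <- function(t, x, params) {
  if (any(!is.finite(t)) || any(t <= 0))
    stop("'t' must be finite and strictly positive", call. = FALSE)
  exp(latency_log_density(t, x, params))
}

# log f_u(t|x); used directly by the likelihood for stability
latency_log_density <- function(t, x, params) {
  eta <- lin_pred(x, params$beta, length(t))
  h0 <- weibull_hazard(t, params$shape, params$scale)
  H <- weibull_cumhaz(t, params$shape, params$scale) * exp(eta)
  lh <- log(h0) + eta
  if (is.finite(params$theta)) {
    lh - (params$theta + 1) * log1p(H / params$theta)
  } else {
    lh - H
  }
}

#' Population (marginal) survival of the mixture
#'
#' The mixture cure model survival
#' \eqn{S_{pop}(t) = \pi(x) + (1 - \pi(x)) S_u(t \mid x)}: a proper survival
#' function levelling off at the cure probability \eqn{\pi(x)} — the plateau a
#' Kaplan-Meier curve of such a population displays.
#'
#' @param t Vector of non-negative times.
#' @param x_inc Incidence covariate vector/matrix.
#' @param x_lat Latency covariate vector/matrix.
#' @param params A [cure_params()] object.
#' @return Survival probabilities; `1` at `t = 0`, limit `pi(x)` as `t` grows.
#' @export
population_survival <- function(t, x_inc, x_lat, params) {
  if (length(params$b) == 0L && length(x_inc) == 0L)
    x_inc <- matrix(numeric(0), nrow = length(t), ncol = 0L)
  pi_x <- cure_probability(x_inc, params$b0, params$b)
  su <- latency_survival(t, x_lat, params)
  pi_x + (1 - pi_x) * su
}

#' Observed-data log-likelihood of the mixture cure rate frailty model
#'
#' For a subject observed at time \eqn{t} with event indicator \eqn{d}, the
#' contribution is \eqn{\log\{(1-\pi) f_u(t)\}} when \eqn{d = 1} and
#' \eqn{\log\{\pi + (1-\pi) S_u(t)\}} when \eqn{d = 0}; the frailty and the
#' latent cure status are marginalised analytically.
#'
#' @param params A [cure_params()] object.
#' @param time Non-negative observed times.
#' @param event 0/1 event indicators (1 = event, 0 = right-censored). Events
#'   recorded at time zero are rejected (the density is degenerate there).
#' @param x_inc Incidence design matrix (no intercept column; `b0` is separate).
#'   May be `NULL` when `params$b` is empty.
#' @param x_lat Latency design matrix; may be `NULL` when `params$beta` is empty.
#' @return The log-likelihood (a finite scalar for valid inputs).
#' @examples
#' p <- cure_params(b0 = 0, shape = 1, scale = 0.5, theta = Inf)
#' cure_loglik(p, time = c(1, 2), event = c(1, 0))
#' @export
cure_loglik <- function(params, time, event, x_inc = NULL, x_lat = NULL) {
  n <- length(time)
  if (n == 0L) stop("empty dataset", call. = FALSE)
  if (length(event) != n) stop("'time' and 'event' lengths differ", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("'event' must be 0/1", call. = FALSE)
  if (any(!is.finite(time)) || any(time < 0))
    stop("'time' must be finite and non-negative", call. = FALSE)
  if (any(time == 0 & event == 1))
    stop("event recorded at time 0: zero-density degenerate case; ",
         "remove or correct these records", call. = FALSE)
  if (is.null(x_inc)) x_inc <- matrix(numeric(0), nrow = n, ncol = 0L)
  if (is.null(x_lat)) x_lat <- matrix(numeric(0), nrow = n, ncol = 0L)
  if (nrow(x_inc) != n || nrow(x_lat) != n)
    stop("design matrix rows do not match length(time)", call. = FALSE)

  lpi <- stats::plogis(params$b0 + lin_pred(x_inc, params$b, n), log.p = TRUE)
  l1mpi <- stats::plogis(params$b0 + lin_pred(x_inc, params$b, n),
                         lower.tail = FALSE, log.p = TRUE)
  ev <- event == 1
  ll <- numeric(n)
  if (any(ev)) {
    ll[ev] <- l1mpi[ev] +
      latency_log_density(time[ev], x_lat[ev, , drop = FALSE], params)
  }
  if (any(!ev)) {
    su <- latency_survival(time[!ev], x_lat[!ev, , drop = FALSE], params)
    # log(pi + (1-pi) su) computed from log terms for stability
    ll[!ev] <- log(exp(lpi[!ev]) + exp(l1mpi[!ev]) * su)
  }
  sum(ll)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop("'", name, "' must be a finite positive scalar", call. = FALSE)
  invisible(x)
}
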