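#' Fit a mixture cure rate frailty model
#'
#' Fits the mixture cure model \eqn{S_{pop}(t \mid x) = \pi(x) + (1 - \pi(x))
#' S_u(t \mid x)} with logistic incidence \eqn{\pi(x)}, Weibull
#' proportional-hazards latency and mean-one gamma frailty on the latency
#' hazard, to right-censored data. Inference is either maximum likelihood
#' (`method = "mle"`: quasi-Newton with multiple jittered starts, Wald
#' intervals from the numerically differentiated observed information) or
#' Bayesian (`method = "bayes"`: adaptive random-walk Metropolis-Hastings on
#' the unconstrained scale; see [curefrail_prior()] and [mh_sample()]).
#' Positive parameters (shape, scale, theta) are handled on the log scale in
#' both routes.
#'
#' @param formula A `Surv(time, event) ~ covariates` formula for the latency
#'   (short-term survivor) component.
#' @param cureform One-sided formula for the incidence (long-term survivor /
#'   cure) component; defaults to the latency covariates.
#' @param data A data.frame containing the variables.
#' @param method `"mle"` or `"bayes"`.
#' @param frailty Logical; `FALSE` fits the frailty-free Weibull mixture cure
#'   model (theta fixed at infinity).
#' @param init Optional [cure_params()] starting value. The default start
#'   uses the Kaplan-Meier plateau for the incidence intercept, zero
#'   coefficients, censoring-ignored method-of-moments Weibull values and
#'   theta = 1.
#' @param control A [curefrail_control()] list (optimizer and sampler
#'   settings).
#' @param prior A [curefrail_prior()] (Bayesian route only).
#' @return An object of class `"curefrail"` (and `"curefrail_bayes"` for the
#'   Bayesian route) with `print`, `summary`, `coef`, `vcov`, `confint`,
#'   `logLik`, `deviance`, `predict`, `residuals`, `simulate` and `plot`
#'   methods.
#' @examples
#' d <- simulate_cohort(gastric_scenario(n = 400), seed = 1)
#' fit <- curefrail(survival::Surv(time, event) ~ chemotherapy + metastasis,
#'                  data = d, control = curefrail_control(n_starts = 1))
#' summary(fit)
#' @export
curefrail <- function(formula, cureform = NULL, data,
                      method = c("mle", "bayes"), frailty = TRUE,
                      init = NULL, control = curefrail_control(),
                      prior = curefrail_prior()) {
  method <- match.arg(method)
  fr <- cure_frame(formula, cureform, data)
  if (all(fr$event == 1))
    stop("all records are events: the cure fraction is unidentifiable ",
         "without a censored plateau", call. = FALSE)
  if (all(fr$event == 0))
    stop("all records are censored: no events to fit the latency component",
         call. = FALSE)
  if (method == "mle")
    curefrail_mle(fr, frailty, init, control, match.call())
  else
    curefrail_bayes(fr, frailty, init, control, prior, match.call())
}

#' Optimizer and sampler settings
#'
#' @param max_iter Maximum optimizer iterations per start / MCMC iterations
#'   are set separately via `n_iter`.
#' @param tol Relative convergence tolerance of the optimizer.
#' @param n_starts Number of jittered starts for the (multimodal) likelihood.
#' @param jitter SD of the Gaussian jitter applied to the default start on
#'   the unconstrained scale.
#' @param seed Seed controlling the jitter and the MCMC (also reported in
#'   output).
#' @param n_iter,burn_in,thin,n_chains Metropolis-Hastings settings.
#' @param proposal_sd Optional vector of proposal SDs on the unconstrained
#'   scale (adapted during burn-in when `adapt = TRUE`).
#' @param adapt Adapt proposal scales during burn-in toward 20-40%
#'   acceptance, then freeze (the post-burn-in kernel is exact MH).
#' @return A list of settings.
#' @export
curefrail_control <- function(max_iter = 500, tol = 1e-8, n_starts = 5,
                              jitter = 0.5, seed = NULL,
                              n_iter = 30000, burn_in = 10000, thin = 5,
                              n_chains = 4, proposal_sd = NULL, adapt = TRUE) {
  list(max_iter = max_iter, tol = tol, n_starts = n_starts, jitter = jitter,
       seed = seed, n_iter = n_iter, burn_in = burn_in, thin = thin,
       n_chains = n_chains, proposal_sd = proposal_sd, adapt = adapt)
}

# ---- model frame -----------------------------------------------------------

cure_frame <- function(formula, cureform, data) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (!survival::is.Surv(y) || attr(y, "type") != "right")
    stop("the response must be a right-censored survival::Surv object",
         call. = FALSE)
  time <- y[, "time"]; event <- y[, "status"]
  validate_surv(time, event)
  Xl <- stats::model.matrix(formula, mf)
  Xl <- Xl[, colnames(Xl) != "(Intercept)", drop = FALSE]
  if (is.null(cureform)) {
    Xi <- Xl
  } else {
    mfi <- stats::model.frame(cureform, data)
    Xi <- stats::model.matrix(cureform, mfi)
    Xi <- Xi[, colnames(Xi) != "(Intercept)", drop = FALSE]
    if (nrow(Xi) != length(time))
      stop("incidence and latency model frames have different sizes ",
           "(missing values?)", call. = FALSE)
  }
  list(time = time, event = event, x_inc = Xi, x_lat = Xl,
       inc_names = colnames(Xi), lat_names = colnames(Xl))
}

# ---- parameter packing -----------------------------------------------------

par_names <- function(fr, frailty) {
  c("cure_(Intercept)",
    if (length(fr$inc_names)) paste0("cure_", fr$inc_names),
    if (length(fr$lat_names)) paste0("surv_", fr$lat_names),
    "log(shape)", "log(scale)", if (frailty) "log(theta)")
}

pack_params <- function(params, frailty) {
  c(params$b0, params$b, params$beta, log(params$shape), log(params$scale),
    if (frailty) log(params$theta))
}

unpack_params <- function(vec, fr, frailty) {
  pi_ <- length(fr$inc_names); pl <- length(fr$lat_names)
  b0 <- vec[1L]
  b <- if (pi_) stats::setNames(vec[1L + seq_len(pi_)], fr$inc_names) else numeric(0)
  beta <- if (pl) stats::setNames(vec[1L + pi_ + seq_len(pl)], fr$lat_names) else numeric(0)
  k <- 1L + pi_ + pl
  cure_params(b0 = b0, b = b, beta = beta,
              shape = exp(vec[k + 1L]), scale = exp(vec[k + 2L]),
              theta = if (frailty) exp(vec[k + 3L]) else Inf)
}

frame_loglik <- function(vec, fr, frailty) {
  p <- try(unpack_params(vec, fr, frailty), silent = TRUE)
  if (inherits(p, "try-error")) return(-Inf)
  ll <- try(cure_loglik(p, fr$time, fr$event, fr$x_inc, fr$x_lat),
            silent = TRUE)
  if (inherits(ll, "try-error") || !is.finite(ll)) return(-Inf)
  ll
}

newton_polish <- function(nll, par, max_steps = 20, gtol = 1e-7) {
  f <- nll(par)
  for (s in seq_len(max_steps)) {
    g <- numDeriv::grad(nll, par)
    if (sqrt(sum(g^2)) < gtol) break
    H <- numDeriv::hessian(nll, par)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    ok <- FALSE
    for (h in 2^-(0:8)) {
      cand <- par - h * step
      fc <- nll(cand)
      if (is.finite(fc) && fc <= f) { par <- cand; f <- fc; ok <- TRUE; break }
    }
    if (!ok) break
  }
  list(par = par, value = f)
}

# default start: plateau-based intercept, zero coefficients,
# censoring-ignored Weibull moments, theta = 1
default_init <- function(fr, frailty) {
  km <- km_curve(fr$time, fr$event)
  plat <- plateau_cure_fraction(km, min_tail_censored = 0)$cure_estimate
  plat <- min(max(plat, 0.05), 0.95)
  te <- fr$time[fr$event == 1]
  cv <- stats::sd(te) / mean(te)
  if (!is.finite(cv) || cv <= 0) cv <- 1
  a <- tryCatch(stats::uniroot(function(a)
    sqrt(gamma(1 + 2 / a) / gamma(1 + 1 / a)^2 - 1) - cv,
    c(0.1, 20))$root, error = function(e) 1)
  lam <- mean(te) / gamma(1 + 1 / a)
  cure_params(b0 = stats::qlogis(plat),
              b = stats::setNames(rep(0, length(fr$inc_names)), fr$inc_names),
              beta = stats::setNames(rep(0, length(fr$lat_names)), fr$lat_names),
              shape = a, scale = lam^(-a), theta = if (frailty) 1 else Inf)
}

# ---- maximum likelihood ----------------------------------------------------

curefrail_mle <- function(fr, frailty, init, control, call) {
  if (is.null(init)) init <- default_init(fr, frailty)
  v0 <- pack_params(init, frailty)
  nms <- par_names(fr, frailty)
  if (!is.finite(frame_loglik(v0, fr, frailty)))
    stop("log-likelihood is not finite at the starting values; supply 'init'",
         call. = FALSE)
  nll <- function(v) -frame_loglik(v, fr, frailty)
  if (!is.null(control$seed)) set.seed(control$seed)
  starts <- c(list(v0), if (control$n_starts > 1)
    replicate(control$n_starts - 1L,
              v0 + stats::rnorm(length(v0), 0, control$jitter),
              simplify = FALSE))
  fits <- lapply(starts, function(s) {
    if (!is.finite(nll(s))) return(NULL)
    tryCatch(stats::optim(s, nll, method = "BFGS",
                          control = list(maxit = control$max_iter,
                                         reltol = control$tol)),
             error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("all optimizer starts failed", call. = FALSE)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  # Newton polish: BFGS stops on a relative-value criterion, which can leave
  # a gradient of order 1e-3 on likelihoods of magnitude 1e3-1e4
  polished <- newton_polish(nll, best$par)
  est <- stats::setNames(polished$par, nms)
  H <- numDeriv::hessian(nll, est)
  vc <- tryCatch(solve(H), error = function(e) NULL)
  se <- if (!is.null(vc) && all(diag(vc) > 0)) sqrt(diag(vc)) else rep(NA_real_, length(est))
  names(se) <- nms
  if (!is.null(vc)) dimnames(vc) <- list(nms, nms)
  converged <- best$convergence == 0 && !is.null(vc) && all(is.finite(se))
  structure(list(call = call, method = "mle", frailty = frailty,
                 estimate = est, se = se, vcov = vc,
                 params = unpack_params(est, fr, frailty),
                 loglik = -best$value, converged = converged,
                 n_iter = best$counts[["function"]],
                 n_starts = length(fits), frame = fr,
                 n = length(fr$time), n_params = length(est)),
            class = "curefrail")
}

#' @export
logLik.curefrail <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n,
            class = "logLik")
}

#' @export
deviance.curefrail <- function(object, ...) -2 * object$loglik

#' @export
coef.curefrail <- function(object, ...) object$estimate

#' @export
vcov.curefrail <- function(object, ...) object$vcov

#' Wald confidence intervals for a fitted cure model
#'
#' Intervals are computed as estimate +/- z * SE on the unconstrained
#' optimization scale; for `log(shape)`, `log(scale)` and `log(theta)` the
#' rows named `shape`, `scale`, `theta` are the exponentiated (hence
#' asymmetric, strictly positive) intervals.
#'
#' @param object A `"curefrail"` MLE fit.
#' @param parm Optional subset of parameter names.
#' @param level Confidence level (default 0.95).
#' @param ... Unused.
#' @return A matrix with columns `estimate`, `lower`, `upper`.
#' @export
confint.curefrail <- function(object, parm = NULL, level = 0.95, ...) {
  if (is.null(object$vcov))
    stop("observed information is singular; intervals unavailable for: ",
         paste(names(object$estimate), collapse = ", "), call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- object$estimate; se <- object$se
  out <- cbind(estimate = est, lower = est - z * se, upper = est + z * se)
  logrows <- grep("^log\\(", rownames(out))
  if (length(logrows)) {
    nat <- exp(out[logrows, , drop = FALSE])
    rownames(nat) <- sub("^log\\((.*)\\)$", "\\1", rownames(out)[logrows])
    out <- rbind(out[-logrows, , drop = FALSE], nat)
  }
  if (!is.null(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
print.curefrail <- function(x, digits = 4, ...) {
  cat("Mixture cure rate", if (x$frailty) "frailty" else "(no-frailty)",
      "model,", if (inherits(x, "curefrail_bayes")) "Bayesian (MH)"
      else "maximum likelihood", "fit\n")
  cat("n =", x$n, "subjects,", sum(x$frame$event), "events\n")
  print(round(coef(x), digits))
  invisible(x)
}

#' @export
summary.curefrail <- function(object, level = 0.95, ...) {
  ci <- confint(object, level = level)
  est <- object$estimate; se <- object$se
  # natural-scale point estimates / delta-method SEs for positive params
  logrows <- grep("^log\\(", names(est))
  keep <- if (length(logrows)) -logrows else seq_along(est)
  nat_names <- sub("^log\\((.*)\\)$", "\\1", names(est)[logrows])
  tab <- data.frame(
    estimate = c(est[keep], exp(est[logrows])),
    sd = c(se[keep], exp(est[logrows]) * se[logrows]),
    row.names = c(names(est)[keep], nat_names))
  tab$lower <- ci[rownames(tab), "lower"]
  tab$upper <- ci[rownames(tab), "upper"]
  structure(list(table = tab, loglik = object$loglik,
                 converged = object$converged, n = object$n,
                 method = object$method, frailty = object$frailty,
                 level = level),
            class = "summary.curefrail")
}

#' @export
print.summary.curefrail <- function(x, digits = 4, ...) {
  cat("Mixture cure rate", if (x$frailty) "frailty" else "(no-frailty)",
      "model —", if (x$method == "mle") "maximum likelihood" else "Bayesian",
      "fit\n")
  print(round(x$table, digits))
  cat("log-likelihood:", format(x$loglik, digits = digits + 2),
      " n =", x$n, "\n")
  if (!is.null(x$converged) && !x$converged)
    cat("WARNING: optimizer did not converge cleanly\n")
  invisible(x)
}

#' Predictions from a fitted cure model
#'
#' @param object A `"curefrail"` fit.
#' @param newdata Data frame of covariates (defaults to the training data
#'   design).
#' @param type `"cure"` for the cure probability \eqn{\pi(x)},
#'   `"survival"` for the population survival \eqn{S_{pop}(t|x)},
#'   `"uncured"` for the latency survival \eqn{S_u(t|x)}.
#' @param times Evaluation times (required for the survival types).
#' @param ... Unused.
#' @return For `"cure"`, a vector; otherwise a matrix (subjects x times).
#' @export
predict.curefrail <- function(object, newdata = NULL,
                              type = c("cure", "survival", "uncured"),
                              times = NULL, ...) {
  type <- match.arg(type)
  fr <- object$frame
  if (is.null(newdata)) {
    Xi <- fr$x_inc; Xl <- fr$x_lat
  } else {
    mm <- stats::model.matrix(~ ., data = newdata)
    Xi <- mm[, fr$inc_names, drop = FALSE]
    Xl <- mm[, fr$lat_names, drop = FALSE]
  }
  p <- object$params
  if (type == "cure") return(cure_probability(Xi, p$b0, p$b))
  if (is.null(times)) stop("'times' required for survival predictions",
                           call. = FALSE)
  out <- sapply(times, function(tt) {
    if (type == "survival")
      population_survival(rep(tt, nrow(Xi)), Xi, Xl, p)
    else latency_survival(rep(tt, nrow(Xl)), Xl, p)
  })
  matrix(out, nrow = nrow(Xi), dimnames = list(NULL, format(times)))
}

#' @export
residuals.curefrail <- function(object, type = c("cox-snell"), ...) {
  type <- match.arg(type)
  fr <- object$frame
  sp <- population_survival(fr$time, fr$x_inc, fr$x_lat, object$params)
  structure(-log(sp), event = fr$event, type = type)
}

#' @export
simulate.curefrail <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  fr <- object$frame; p <- object$params
  n <- length(fr$time)
  out <- replicate(nsim, {
    pi_x <- cure_probability(fr$x_inc, p$b0, p$b)
    cured <- stats::rbinom(n, 1, pi_x) == 1
    w <- if (is.finite(p$theta)) stats::rgamma(n, p$theta, rate = p$theta)
         else rep(1, n)
    eta <- lin_pred(fr$x_lat, p$beta, n)
    tev <- (stats::rexp(n) / (w * exp(eta) * p$scale))^(1 / p$shape)
    tev[cured] <- Inf
    # observed censoring times are reused as the censoring mechanism
    cens <- ifelse(fr$event == 0, fr$time, Inf)
    data.frame(time = pmin(tev, cens, max(fr$time)),
               event = as.integer(tev <= pmin(cens, max(fr$time))))
  }, simplify = FALSE)
  if (nsim == 1) out[[1]] else out
}

#' @export
plot.curefrail <- function(x, times = NULL, ...) {
  fr <- x$frame
  km <- km_curve(fr$time, fr$event)
  plot(km, ...)
  if (is.null(times)) times <- seq(0, max(fr$time), length.out = 200)
  sp <- colMeans(predict(x, type = "survival", times = times))
  graphics::lines(times, sp, lty = 2)
  graphics::legend("topright", legend = c("Kaplan-Meier", "fitted"),
                   lty = 1:2, bty = "n")
  invisible(x)
}
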