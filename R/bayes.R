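#' Prior specification for the Bayesian cure model
#'
#' Weakly informative defaults: independent Normal(0, `coef_sd`^2) priors on
#' the incidence intercept and all regression coefficients, and Normal(0,
#' `log_sd`^2) priors on log(shape), log(scale) and log(theta) — i.e. the
#' positive parameters carry their prior on the log scale, which is also the
#' sampling scale (so no Jacobian term is needed in the target).
#'
#' @param coef_sd Prior SD for coefficients (default 10).
#' @param log_sd Prior SD for log-scale positive parameters (default 10).
#' @return An object of class `"cure_prior"`.
#' @export
curefrail_prior <- function(coef_sd = 10, log_sd = 10) {
  if (coef_sd <= 0 || log_sd <= 0) stop("prior SDs must be positive",
                                        call. = FALSE)
  structure(list(coef_sd = coef_sd, log_sd = log_sd), class = "cure_prior")
}

#' Log-posterior of the cure model (up to a constant)
#'
#' Log-likelihood plus log prior density under a [curefrail_prior()]. The
#' prior on shape/scale/theta is evaluated on the log scale.
#'
#' @param params A [cure_params()] object.
#' @param time,event,x_inc,x_lat Data as in [cure_loglik()]; pass `time =
#'   NULL` for a priors-only target.
#' @param prior A [curefrail_prior()].
#' @return Scalar log-posterior; `-Inf` outside the support.
#' @export
cure_log_posterior <- function(params, time, event, x_inc = NULL,
                               x_lat = NULL, prior = curefrail_prior()) {
  lp <- sum(stats::dnorm(c(params$b0, params$b, params$beta),
                         0, prior$coef_sd, log = TRUE)) +
    sum(stats::dnorm(log(c(params$shape, params$scale,
                           if (is.finite(params$theta)) params$theta)),
                     0, prior$log_sd, log = TRUE))
  if (is.null(time)) return(lp)
  lp + cure_loglik(params, time, event, x_inc, x_lat)
}

#' Random-walk Metropolis-Hastings sampler
#'
#' Gaussian block random-walk on an unconstrained parameter vector. During
#' burn-in (when `adapt = TRUE`) a global step-size multiplier is tuned by a
#' Robbins-Monro rule toward `target_accept`, and per-coordinate scales are
#' refreshed from the accumulated draws; both are frozen at the end of
#' burn-in so the retained draws come from an exact MH kernel.
#'
#' @param log_target Function mapping a parameter vector to its (unnormalised)
#'   log density; may return `-Inf` (proposal rejected), never `NaN`.
#' @param init Numeric starting vector (finite target required).
#' @param n_iter Total iterations (must exceed `burn_in`).
#' @param burn_in Iterations discarded (and used for adaptation).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param proposal_sd Per-coordinate proposal SDs (positive); default 0.1.
#' @param seed Optional seed for exact reproducibility.
#' @param adapt Adapt during burn-in (default TRUE).
#' @param target_accept Acceptance rate targeted by adaptation (default 0.3).
#' @return An object of class `"posterior_chain"`: list with `draws` (matrix,
#'   post-burn-in, thinned), `acceptance_rate` (post-burn-in), `burn_in`,
#'   `thin`, `seed`, `proposal_sd` (final), `n_iter`.
#' @export
mh_sample <- function(log_target, init, n_iter = 30000, burn_in = 10000,
                      thin = 5, proposal_sd = NULL, seed = NULL,
                      adapt = TRUE, target_accept = 0.3) {
  d <- length(init)
  if (is.null(proposal_sd)) proposal_sd <- rep(0.1, d)
  if (length(proposal_sd) == 1L) proposal_sd <- rep(proposal_sd, d)
  if (any(proposal_sd <= 0)) stop("proposal SDs must be positive", call. = FALSE)
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  lp <- log_target(init)
  if (!is.finite(lp)) stop("log target is not finite at 'init'", call. = FALSE)

  x <- init
  scale_mult <- 1
  keep <- matrix(NA_real_, nrow = floor((n_iter - burn_in) / thin), ncol = d)
  colnames(keep) <- names(init)
  warm <- matrix(NA_real_, nrow = burn_in, ncol = d)
  k <- 0L; acc_post <- 0L; n_post <- 0L
  acc_batch <- 0L; batch <- 0L; batch_size <- 50L
  for (i in seq_len(n_iter)) {
    prop <- x + stats::rnorm(d, 0, scale_mult * proposal_sd)
    lpp <- log_target(prop)
    accept <- is.finite(lpp) && log(stats::runif(1)) < lpp - lp
    if (accept) { x <- prop; lp <- lpp }
    if (i <= burn_in) {
      warm[i, ] <- x
      if (adapt) {
        acc_batch <- acc_batch + accept
        if (i %% batch_size == 0L) {
          batch <- batch + 1L
          scale_mult <- scale_mult *
            exp((acc_batch / batch_size - target_accept) / sqrt(batch))
          acc_batch <- 0L
          # refresh coordinate scales from the second half of warm-up so far
          if (batch %% 10L == 0L && i >= 500L) {
            s <- apply(warm[floor(i / 2):i, , drop = FALSE], 2, stats::sd)
            if (all(is.finite(s)) && all(s > 0))
              proposal_sd <- s * 2.38 / sqrt(d)
          }
        }
      }
    } else {
      n_post <- n_post + 1L
      acc_post <- acc_post + accept
      if (n_post %% thin == 0L) { k <- k + 1L; keep[k, ] <- x }
    }
  }
  chain <- structure(list(draws = keep[seq_len(k), , drop = FALSE],
                          acceptance_rate = acc_post / n_post,
                          burn_in = burn_in, thin = thin, n_iter = n_iter,
                          seed = seed, proposal_sd = scale_mult * proposal_sd),
                     class = "posterior_chain")
  if (chain$acceptance_rate == 0)
    warning("no proposals accepted after burn-in; the chain is stuck",
            call. = FALSE)
  chain
}

#' @export
print.posterior_chain <- function(x, ...) {
  cat("MH posterior chain:", nrow(x$draws), "retained draws of",
      ncol(x$draws), "parameters\n")
  cat(sprintf("n_iter %d, burn-in %d, thin %d, acceptance %.1f%%\n",
              x$n_iter, x$burn_in, x$thin, 100 * x$acceptance_rate))
  invisible(x)
}

#' Posterior summary of a chain
#'
#' Mean, SD and equal-tailed 95% percentile interval per parameter.
#'
#' @param chain A `"posterior_chain"`, a draws matrix, or a list of chains
#'   (pooled).
#' @param level Credible level (default 0.95).
#' @return A data.frame with columns `mean`, `sd`, `lower`, `upper`.
#' @export
posterior_summary <- function(chain, level = 0.95) {
  draws <- pool_draws(chain)
  if (nrow(draws) < 100L)
    stop("chain too short to summarize (need >= 100 post-burn-in draws)",
         call. = FALSE)
  a <- (1 - level) / 2
  data.frame(mean = colMeans(draws),
             sd = apply(draws, 2, stats::sd),
             lower = apply(draws, 2, stats::quantile, probs = a),
             upper = apply(draws, 2, stats::quantile, probs = 1 - a),
             row.names = colnames(draws))
}

pool_draws <- function(chain) {
  if (inherits(chain, "posterior_chain")) return(chain$draws)
  if (is.list(chain) && all(vapply(chain, inherits, TRUE, "posterior_chain")))
    return(do.call(rbind, lapply(chain, `[[`, "draws")))
  as.matrix(chain)
}

#' MCMC convergence diagnostics
#'
#' Split-chain potential scale reduction (Rhat) and effective sample size
#' from the pooled autocorrelation (Geyer-style truncation at the first
#' negative paired sum), plus acceptance rates. Threshold violations warn,
#' never error.
#'
#' @param chains A `"posterior_chain"` or list thereof.
#' @param rhat_warn Warn when any split-Rhat exceeds this (default 1.1).
#' @param ess_warn Warn when any ESS falls below this (default 100).
#' @return A data.frame (`rhat`, `ess` per parameter) with attribute
#'   `"acceptance_rates"`.
#' @export
mcmc_diagnostics <- function(chains, rhat_warn = 1.1, ess_warn = 100) {
  if (inherits(chains, "posterior_chain")) chains <- list(chains)
  mats <- lapply(chains, `[[`, "draws")
  nmin <- min(vapply(mats, nrow, 1L))
  mats <- lapply(mats, function(m) m[seq_len(nmin), , drop = FALSE])
  out <- data.frame(rhat = split_rhat(mats), ess = multi_ess(mats),
                    row.names = colnames(mats[[1]]))
  attr(out, "acceptance_rates") <-
    vapply(chains, `[[`, numeric(1), "acceptance_rate")
  if (any(attr(out, "acceptance_rates") == 0))
    warning("a chain accepted no proposals", call. = FALSE)
  if (any(is.finite(out$rhat) & out$rhat > rhat_warn))
    warning("split-Rhat above ", rhat_warn, " for: ",
            paste(rownames(out)[out$rhat > rhat_warn], collapse = ", "),
            call. = FALSE)
  if (any(out$ess < ess_warn))
    warning("effective sample size below ", ess_warn, " for: ",
            paste(rownames(out)[out$ess < ess_warn], collapse = ", "),
            call. = FALSE)
  out
}

# split each chain in half, compute classic Rhat across the split chains
split_rhat <- function(mats) {
  halves <- unlist(lapply(mats, function(m) {
    n2 <- floor(nrow(m) / 2)
    list(m[seq_len(n2), , drop = FALSE],
         m[n2 + seq_len(n2), , drop = FALSE])
  }), recursive = FALSE)
  m <- length(halves); n <- nrow(halves[[1]])
  vapply(seq_len(ncol(halves[[1]])), function(j) {
    x <- vapply(halves, function(h) c(mean(h[, j]), stats::var(h[, j])),
                numeric(2))
    B <- n * stats::var(x[1, ]); W <- mean(x[2, ])
    if (W == 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
}

# ESS via chain-averaged autocorrelations, truncated at the first negative
# paired sum (rho_{2k} + rho_{2k+1} < 0)
multi_ess <- function(mats) {
  n <- nrow(mats[[1]]); m <- length(mats)
  vapply(seq_len(ncol(mats[[1]])), function(j) {
    rho <- rowMeans(vapply(mats, function(mat) {
      a <- stats::acf(mat[, j], lag.max = min(n - 1, 1000), plot = FALSE,
                      demean = TRUE)$acf[, 1, 1]
      if (stats::var(mat[, j]) == 0) a[] <- 0
      a
    }, numeric(min(n - 1, 1000) + 1)))
    s <- 0; k <- 1
    while (k + 1 < length(rho)) {
      pair <- rho[k + 1] + ifelse(k + 2 <= length(rho), rho[k + 2], 0)
      if (!is.finite(pair) || pair < 0) break
      s <- s + pair; k <- k + 2
    }
    max(1, m * n / (1 + 2 * s))
  }, numeric(1))
}

# ---- Bayesian fit of the cure model ---------------------------------------

curefrail_bayes <- function(fr, frailty, init, control, prior, call) {
  if (is.null(init)) init <- default_init(fr, frailty)
  v0 <- pack_params(init, frailty)
  nms <- par_names(fr, frailty)
  names(v0) <- nms
  logrows <- grep("^log\\(", nms)
  target <- function(v) {
    ll <- frame_loglik(v, fr, frailty)
    if (!is.finite(ll)) return(-Inf)
    ll + sum(stats::dnorm(v[-logrows], 0, prior$coef_sd, log = TRUE)) +
      sum(stats::dnorm(v[logrows], 0, prior$log_sd, log = TRUE))
  }
  if (!is.finite(target(v0)))
    stop("posterior is not finite at the starting values", call. = FALSE)
  base_seed <- if (is.null(control$seed)) sample.int(1e6, 1) else control$seed
  chains <- lapply(seq_len(control$n_chains), function(k) {
    set.seed(base_seed + k)
    start <- v0 + stats::rnorm(length(v0), 0, if (control$n_chains > 1) 0.2 else 0)
    while (!is.finite(target(start)))
      start <- v0 + stats::rnorm(length(v0), 0, 0.1)
    mh_sample(target, start, n_iter = control$n_iter,
              burn_in = control$burn_in, thin = control$thin,
              proposal_sd = control$proposal_sd, seed = base_seed + 1000L + k,
              adapt = control$adapt)
  })
  draws <- pool_draws(chains)
  post_mean <- colMeans(draws)
  # reporting-scale draws: positive params exponentiated
  rep_draws <- draws
  rep_draws[, logrows] <- exp(rep_draws[, logrows])
  colnames(rep_draws) <- sub("^log\\((.*)\\)$", "\\1", nms)
  structure(list(call = call, method = "bayes", frailty = frailty,
                 prior = prior, chains = chains, draws = draws,
                 rep_draws = rep_draws,
                 estimate = post_mean,
                 se = apply(draws, 2, stats::sd),
                 params = unpack_params(post_mean, fr, frailty),
                 loglik = frame_loglik(post_mean, fr, frailty),
                 seed = base_seed, frame = fr, n = length(fr$time),
                 n_params = length(v0),
                 diagnostics = suppressWarnings(mcmc_diagnostics(chains))),
            class = c("curefrail_bayes", "curefrail"))
}

#' @export
confint.curefrail_bayes <- function(object, parm = NULL, level = 0.95, ...) {
  ps <- posterior_summary(object$rep_draws, level = level)
  out <- cbind(estimate = ps$mean, lower = ps$lower, upper = ps$upper)
  rownames(out) <- rownames(ps)
  if (!is.null(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
summary.curefrail_bayes <- function(object, level = 0.95, ...) {
  ps <- posterior_summary(object$rep_draws, level = level)
  names(ps) <- c("estimate", "sd", "lower", "upper")
  structure(list(table = ps, loglik = object$loglik, converged = NULL,
                 n = object$n, method = "bayes", frailty = object$frailty,
                 level = level, diagnostics = object$diagnostics),
            class = c("summary.curefrail_bayes", "summary.curefrail"))
}

#' @export
print.summary.curefrail_bayes <- function(x, digits = 4, ...) {
  NextMethod()
  cat("max split-Rhat:", round(max(x$diagnostics$rhat), 3),
      " min ESS:", round(min(x$diagnostics$ess)), "\n")
  invisible(x)
}

# ---- chain persistence -----------------------------------------------------

#' Write / read a posterior chain as delimited text
#'
#' The draws go to a CSV with a parameter-name header; seed, burn-in,
#' thinning, acceptance rate and proposal SDs go to a `<path>.meta.json`
#' sidecar so a chain can be re-summarized exactly.
#'
#' @param chain A `"posterior_chain"`.
#' @param path CSV path.
#' @return `write_chain` returns `path` invisibly; `read_chain` the restored
#'   `"posterior_chain"`.
#' @export
write_chain <- function(chain, path) {
  stopifnot(inherits(chain, "posterior_chain"))
  utils::write.csv(as.data.frame(chain$draws), path, row.names = FALSE)
  meta <- chain[setdiff(names(chain), "draws")]
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_chain
#' @export
read_chain <- function(path) {
  draws <- as.matrix(utils::read.csv(path, check.names = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  structure(c(list(draws = draws), meta), class = "posterior_chain")
}
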