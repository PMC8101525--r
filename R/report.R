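#' Cure odds ratio for one incidence covariate
#'
#' The logistic incidence link makes \eqn{e^{b_j}} the odds ratio of being
#' cured (long-term survivor) for the level coded by dummy column `variable`
#' against its reference. For an MLE fit the interval is the exponentiated
#' Wald interval; for a Bayesian fit it is the percentile interval of the
#' exponentiated draws. `direction = "ref-vs-level"` returns the reciprocal
#' (the odds ratio quoted for the reference level against the coded level).
#'
#' @param fit A `"curefrail"` fit.
#' @param variable Name of an incidence dummy column (as in
#'   `fit$frame$inc_names`).
#' @param direction `"level-vs-ref"` (default) or `"ref-vs-level"`.
#' @param level Interval level.
#' @return Named vector `estimate`, `lower`, `upper`.
#' @export
odds_ratio_summary <- function(fit, variable,
                               direction = c("level-vs-ref", "ref-vs-level"),
                               level = 0.95) {
  direction <- match.arg(direction)
  if (!variable %in% fit$frame$inc_names)
    stop("unknown incidence variable: ", variable, call. = FALSE)
  nm <- paste0("cure_", variable)
  if (inherits(fit, "curefrail_bayes")) {
    dr <- exp(fit$draws[, nm])
    a <- (1 - level) / 2
    out <- c(estimate = mean(dr),
             lower = unname(stats::quantile(dr, a)),
             upper = unname(stats::quantile(dr, 1 - a)))
  } else {
    ci <- confint(fit, parm = nm, level = level)
    out <- exp(c(estimate = ci[1, "estimate"], lower = ci[1, "lower"],
                 upper = ci[1, "upper"]))
  }
  if (direction == "ref-vs-level")
    out <- c(estimate = 1 / out[["estimate"]], lower = 1 / out[["upper"]],
             upper = 1 / out[["lower"]])
  out
}

#' Cure probability at a covariate profile
#'
#' Posterior (Bayesian: transformed-draw percentiles) or Wald/delta (MLE:
#' normal interval on the logit scale, mapped through the inverse link)
#' summary of \eqn{\pi(x)} at a stated incidence profile. Unspecified
#' covariates sit at their reference level (zero).
#'
#' @param fit A `"curefrail"` fit.
#' @param profile Named vector/list of incidence dummy values (e.g.
#'   `c(chemotherapyyes = 1)`); empty for the all-reference profile.
#' @param level Interval level.
#' @return Named vector `estimate`, `lower`, `upper`.
#' @export
cure_probability_summary <- function(fit, profile = NULL, level = 0.95) {
  inc <- fit$frame$inc_names
  x <- stats::setNames(rep(0, length(inc)), inc)
  if (length(profile)) {
    profile <- unlist(profile)
    bad <- setdiff(names(profile), inc)
    if (length(bad))
      stop("profile names not incidence covariates: ",
           paste(bad, collapse = ", "), call. = FALSE)
    x[names(profile)] <- profile
  }
  a <- (1 - level) / 2
  if (inherits(fit, "curefrail_bayes")) {
    cols <- c("cure_(Intercept)", paste0("cure_", inc))
    eta <- fit$draws[, cols, drop = FALSE] %*% c(1, x)
    pr <- stats::plogis(eta)
    c(estimate = mean(pr), lower = unname(stats::quantile(pr, a)),
      upper = unname(stats::quantile(pr, 1 - a)))
  } else {
    cols <- c("cure_(Intercept)", paste0("cure_", inc))
    v <- c(1, x)
    eta <- sum(fit$estimate[cols] * v)
    se <- sqrt(drop(t(v) %*% fit$vcov[cols, cols] %*% v))
    z <- stats::qnorm(1 - a)
    stats::setNames(stats::plogis(c(eta, eta - z * se, eta + z * se)),
                    c("estimate", "lower", "upper"))
  }
}

#' Long-term survivor table (odds ratios and cure probabilities)
#'
#' One row per incidence dummy level plus its reference: the cure odds ratio
#' (reference fixed at exactly 1) and the cure probability at the profile
#' where that variable takes the stated level and every other variable its
#' reference.
#'
#' @param fit A `"curefrail"` fit.
#' @param level Interval level.
#' @return A data.frame with columns `variable`, `or`, `or_lower`,
#'   `or_upper`, `cure_prob`, `cure_lower`, `cure_upper`.
#' @export
long_term_table <- function(fit, level = 0.95) {
  inc <- fit$frame$inc_names
  rows <- lapply(inc, function(v) {
    or <- odds_ratio_summary(fit, v, level = level)
    pr <- cure_probability_summary(fit, stats::setNames(1, v), level = level)
    pr0 <- cure_probability_summary(fit, NULL, level = level)
    data.frame(variable = c(v, paste0(v, " (reference)")),
               or = c(or[["estimate"]], 1),
               or_lower = c(or[["lower"]], NA),
               or_upper = c(or[["upper"]], NA),
               cure_prob = c(pr[["estimate"]], pr0[["estimate"]]),
               cure_lower = c(pr[["lower"]], pr0[["lower"]]),
               cure_upper = c(pr[["upper"]], pr0[["upper"]]))
  })
  do.call(rbind, rows)
}

#' Short-term survivor table (latency, baseline and frailty parameters)
#'
#' Estimate / SD / 95% interval for the Weibull baseline parameters, the
#' frailty shape, the incidence intercept and the latency coefficients, with
#' one column block per supplied fit (e.g. classical and Bayesian side by
#' side). Reference levels are implicit (coefficient 0); a row of zeros per
#' fitted dummy's reference is appended for table completeness.
#'
#' @param ... Named `"curefrail"` fits.
#' @param level Interval level.
#' @return A data.frame; columns `parameter` then
#'   `<fit>_est`, `<fit>_sd`, `<fit>_lower`, `<fit>_upper` per fit.
#' @export
short_term_table <- function(..., level = 0.95) {
  fits <- list(...)
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- paste0("model", seq_along(fits))
  tabs <- lapply(fits, function(f) summary(f, level = level)$table)
  rows <- unique(unlist(lapply(tabs, rownames)))
  keep <- c(intersect(c("scale", "theta", "shape", "cure_(Intercept)"), rows),
            grep("^surv_", rows, value = TRUE))
  out <- data.frame(parameter = keep)
  for (nm in names(tabs)) {
    tt <- tabs[[nm]][keep, ]
    out[[paste0(nm, "_est")]] <- tt$estimate
    out[[paste0(nm, "_sd")]] <- tt$sd
    out[[paste0(nm, "_lower")]] <- tt$lower
    out[[paste0(nm, "_upper")]] <- tt$upper
  }
  out
}

#' Write the report tables of a fitted analysis to CSV
#'
#' Emits the cohort characteristics, short-term, long-term and
#' information-criterion tables as machine-readable CSVs (full precision).
#'
#' @param dir Output directory (created if needed).
#' @param cohort A [cohort_summary()] object.
#' @param short A [short_term_table()] data.frame.
#' @param long A [long_term_table()] data.frame.
#' @param ic A [compare_ic()] data.frame.
#' @return The directory, invisibly.
#' @export
write_report_tables <- function(dir, cohort = NULL, short = NULL,
                                long = NULL, ic = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cohort)) {
    base <- data.frame(statistic = c("n_total", "n_events", "n_censored",
                                     "event_rate", "censored_rate",
                                     "time_mean", "time_sd"),
                       value = c(cohort$n_total, cohort$n_events,
                                 cohort$n_censored, cohort$event_rate,
                                 cohort$censored_rate, cohort$time_mean,
                                 cohort$time_sd))
    utils::write.csv(base, file.path(dir, "table1_cohort.csv"),
                     row.names = FALSE)
  }
  if (!is.null(short))
    utils::write.csv(short, file.path(dir, "table2_short_term.csv"),
                     row.names = FALSE)
  if (!is.null(long))
    utils::write.csv(long, file.path(dir, "table3_long_term.csv"),
                     row.names = FALSE)
  if (!is.null(ic))
    utils::write.csv(cbind(criterion = rownames(ic), ic),
                     file.path(dir, "table4_criteria.csv"), row.names = FALSE)
  invisible(dir)
}
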