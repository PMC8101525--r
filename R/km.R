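#' Kaplan-Meier curve
#'
#' Product-limit estimate of the survival function, the standard first look
#' at a cohort suspected to contain cured (never-event) subjects: a curve
#' that levels off at a plateau above zero instead of dropping to zero is
#' the visual signature of a cure fraction. Ties of events and censorings at
#' the same time are handled events-first, as usual.
#'
#' @param time Non-negative observed times.
#' @param event 0/1 event indicators.
#' @return An object of class `"km_curve"`: a list with `times` (sorted
#'   distinct observed times), `surv` (step-function values), `n_risk`,
#'   `n_event`, `n_censor`, and `n` (cohort size).
#' @examples
#' km <- km_curve(c(1, 2, 3), c(1, 0, 1))
#' km$surv # 2/3 at t = 1, then 0 at t = 3
#' @export
km_curve <- function(time, event) {
  validate_km(time, event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  structure(list(times = fit$time, surv = fit$surv,
                 n_risk = fit$n.risk, n_event = fit$n.event,
                 n_censor = fit$n.censor, n = length(time)),
            class = "km_curve")
}

validate_km <- function(time, event) {
  if (length(time) == 0L) stop("empty dataset", call. = FALSE)
  if (any(!is.finite(time)) || any(time < 0))
    stop("'time' must be finite and non-negative", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("'event' must be 0/1", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", x$n, "subjects,", sum(x$n_event), "events\n")
  le <- last_event_time(x)
  if (is.finite(le))
    cat(sprintf("Survival at last event time (%.2f): %.4f\n",
                le, km_survival_at(x, le)))
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param curve A [km_curve()] object.
#' @param t Times at which to evaluate the step function.
#' @return Survival probabilities (1 before the first observed time).
#' @export
km_survival_at <- function(curve, t) {
  vapply(t, function(tt) {
    i <- which(curve$times <= tt)
    if (length(i) == 0L) 1 else curve$surv[max(i)]
  }, numeric(1))
}

last_event_time <- function(curve) {
  i <- which(curve$n_event > 0)
  if (length(i) == 0L) -Inf else max(curve$times[i])
}

#' Plateau-based cure fraction estimate
#'
#' Operationalises the visual "stable plateau" check: the cure fraction is
#' estimated by the Kaplan-Meier value at the last observed event time, and
#' follow-up is declared sufficient when at least `min_tail_censored`
#' censored observations lie strictly beyond that time (so the plateau is a
#' supported flat stretch, not an artifact of follow-up ending).
#'
#' @param curve A [km_curve()] object.
#' @param min_tail_censored Minimum number of censored observations beyond
#'   the last event time required to trust the plateau (default 5).
#' @return An object of class `"plateau_report"`: list with `cure_estimate`,
#'   `last_event_time`, `censored_beyond`, `sufficient_followup`.
#' @export
plateau_cure_fraction <- function(curve, min_tail_censored = 5) {
  stopifnot(inherits(curve, "km_curve"))
  le <- last_event_time(curve)
  if (!is.finite(le)) {
    warning("no events observed; cure fraction estimate is 1", call. = FALSE)
    cb <- sum(curve$n_censor)
    return(structure(list(cure_estimate = 1, last_event_time = NA_real_,
                          censored_beyond = cb,
                          sufficient_followup = cb >= min_tail_censored),
                     class = "plateau_report"))
  }
  cb <- sum(curve$n_censor[curve$times > le])
  structure(list(cure_estimate = km_survival_at(curve, le),
                 last_event_time = le,
                 censored_beyond = cb,
                 sufficient_followup = cb >= min_tail_censored),
            class = "plateau_report")
}

#' @export
print.plateau_report <- function(x, ...) {
  cat(sprintf("KM plateau cure-fraction estimate: %.3f\n", x$cure_estimate))
  cat(sprintf("Last event at %s months; %d censored beyond it (%s follow-up)\n",
              format(x$last_event_time), x$censored_beyond,
              if (x$sufficient_followup) "sufficient" else "INSUFFICIENT"))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, xlab = "Months", ylab = "Survival probability",
                          ...) {
  ts <- c(0, rep(x$times, each = 2))
  ss <- c(1, 1, rep(x$surv, each = 2)[-(2 * length(x$surv))])
  plot(ts, ss, type = "l", ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' @export
as.data.frame.km_curve <- function(x, ...) {
  data.frame(time = x$times, surv = x$surv, n_risk = x$n_risk,
             n_event = x$n_event, n_censor = x$n_censor)
}
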