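#' Read a right-censored survival dataset from CSV
#'
#' Expects a header row with columns `time` (months, non-negative), `event`
#' (0 = censored, 1 = event) and any number of covariate columns. Character
#' columns are converted to factors (first level in alphabetical order is the
#' reference unless `ref_levels` names another). Missing values are rejected —
#' no imputation rule is assumed — as are events recorded at time zero.
#'
#' @param path Path to a CSV file.
#' @param ref_levels Optional named list, `list(covariate = "reference level")`,
#'   recorded in the returned frame's `"ref_levels"` attribute and used to
#'   relevel factors.
#' @return A `data.frame` with `time`, `event` and covariate columns.
#' @export
read_cure_data <- function(path, ref_levels = NULL) {
  dat <- utils::read.csv(path, stringsAsFactors = TRUE)
  need <- c("time", "event")
  miss <- setdiff(need, names(dat))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyNA(dat)) {
    bad <- which(!stats::complete.cases(dat))
    stop("missing values in row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "", "; no imputation is performed",
         call. = FALSE)
  }
  validate_surv(dat$time, dat$event)
  for (nm in names(ref_levels)) {
    if (!nm %in% names(dat)) stop("unknown covariate in ref_levels: ", nm,
                                  call. = FALSE)
    dat[[nm]] <- stats::relevel(factor(dat[[nm]]), ref = ref_levels[[nm]])
  }
  attr(dat, "ref_levels") <- ref_levels
  dat
}

validate_surv <- function(time, event) {
  if (length(time) == 0L) stop("empty dataset", call. = FALSE)
  if (!is.numeric(time) || any(!is.finite(time)) || any(time < 0))
    stop("'time' must be numeric, finite and non-negative", call. = FALSE)
  if (!all(event %in% c(0, 1)))
    stop("'event' must be coded 0 (censored) / 1 (event)", call. = FALSE)
  if (any(time == 0 & event == 1))
    stop("event recorded at time 0; remove or correct these records",
         call. = FALSE)
  invisible(TRUE)
}

#' Covariate cross-tabulation of the gastric-cancer study population
#'
#' The published characteristics of the 339-patient Kerman gastric-cancer
#' cohort (2001--2015): per covariate level, the number of patients who died
#' of gastric cancer and the number censored. These printed counts are the
#' only patient-level information publicly available for that registry; they
#' drive both the synthetic cohort's covariate margins and the exact cohort
#' arithmetic (event rate 57.5%, censored 42.5%).
#'
#' @return A `data.frame` with columns `variable`, `level`, `died`, `censored`.
#' @examples
#' tab <- gastric_table1()
#' sum(tab$died[tab$variable == "sex"]) # 195 deaths
#' @export
gastric_table1 <- function() {
  data.frame(
    variable = rep(c("sex", "opium", "smoker", "residence", "surgery",
                     "radiotherapy", "chemotherapy", "metastasis",
                     "family_history", "grade", "stage", "morphology",
                     "age_group"),
                   times = c(2, 2, 2, 2, 2, 2, 2, 2, 2, 3, 4, 3, 2)),
    level = c("male", "female", "no", "yes", "no", "yes", "urban", "rural",
              "no", "yes", "no", "yes", "no", "yes", "no", "yes", "no", "yes",
              "well", "moderate", "poor", "I", "II", "III", "IV",
              "neoplasm", "carcinoma", "adenocarcinoma", "<60", ">=60"),
    died = c(121, 74, 120, 75, 142, 53, 161, 34, 39, 156, 167, 28, 117, 78,
             110, 85, 176, 19, 6, 151, 38, 6, 111, 56, 22, 20, 32, 143,
             80, 115),
    censored = c(95, 49, 95, 49, 106, 38, 111, 33, 26, 118, 126, 18, 87, 57,
                 95, 49, 134, 10, 5, 119, 20, 3, 94, 35, 12, 3, 21, 120,
                 54, 90),
    stringsAsFactors = FALSE
  )
}

#' Reconstruct a minimal cohort from sex-stratified counts
#'
#' Expands the died/censored counts of one cross-tabulated variable into a
#' subject-level data.frame (one row per patient, unit times for the dead,
#' so only the event indicator carries information). Used for exact count
#' arithmetic such as the study's event and censoring rates.
#'
#' @param variable Which [gastric_table1()] variable to expand
#'   (default `"sex"`).
#' @return A `data.frame` with `time`, `event` and the chosen covariate.
#' @export
gastric_cohort_counts <- function(variable = "sex") {
  tab <- gastric_table1()
  tab <- tab[tab$variable == variable, ]
  if (nrow(tab) == 0L) stop("unknown variable: ", variable, call. = FALSE)
  lev <- rep(tab$level, times = tab$died + tab$censored)
  ev <- unlist(mapply(function(d, c) rep(c(1, 0), times = c(d, c)),
                      tab$died, tab$censored, SIMPLIFY = FALSE))
  out <- data.frame(time = ifelse(ev == 1, 1, 2), event = ev)
  out[[variable]] <- factor(lev, levels = tab$level)
  out
}

#' Cohort descriptives
#'
#' Counts, event/censoring rates and per-covariate cross-tabs by event
#' status, in the shape of a study characteristics table.
#'
#' @param data A data.frame with `time`, `event` and covariate columns.
#' @param covariates Character vector of covariate columns to cross-tabulate;
#'   defaults to all non-time/event columns.
#' @return An object of class `"cohort_summary"`: a list with `n_total`,
#'   `n_events`, `n_censored`, `event_rate`, `censored_rate`, `time_mean`,
#'   `time_sd` and a `crosstabs` list of died/censored counts per covariate.
#' @export
cohort_summary <- function(data, covariates = NULL) {
  validate_surv(data$time, data$event)
  if (is.null(covariates))
    covariates <- setdiff(names(data), c("time", "event"))
  n <- nrow(data)
  ne <- sum(data$event == 1)
  xt <- lapply(covariates, function(v) {
    t(table(factor(ifelse(data$event == 1, "died", "censored"),
                   levels = c("died", "censored")), data[[v]]))
  })
  names(xt) <- covariates
  structure(list(n_total = n, n_events = ne, n_censored = n - ne,
                 event_rate = ne / n, censored_rate = (n - ne) / n,
                 time_mean = mean(data$time), time_sd = stats::sd(data$time),
                 crosstabs = xt),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, digits = 3, ...) {
  cat("Cohort of", x$n_total, "subjects:",
      x$n_events, sprintf("events (%.1f%%),", 100 * x$event_rate),
      x$n_censored, sprintf("censored (%.1f%%)\n", 100 * x$censored_rate))
  cat(sprintf("Observed time: mean %.2f, SD %.2f months\n",
              x$time_mean, x$time_sd))
  for (v in names(x$crosstabs)) {
    cat("\n", v, ":\n", sep = "")
    print(x$crosstabs[[v]])
  }
  invisible(x)
}
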