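#' Information criteria for fitted cure models
#'
#' For a Bayesian fit, the deviance \eqn{D(\vartheta) = -2 \log L(\vartheta)}
#' is averaged over the posterior draws (`dbar`); the effective number of
#' parameters is `pd = dbar - D(posterior mean)` (Spiegelhalter's form, with
#' the posterior mean taken on the unconstrained sampling scale and
#' back-transformed), and
#' \deqn{DIC = dbar + pd, \quad EAIC = dbar + 2p, \quad
#'   EBIC = dbar + p \log n.}
#' For a maximum-likelihood fit the same report is produced by the plug-in
#' convention: `dbar` is the deviance at the MLE and `pd = 0` (so DIC is the
#' minimised deviance, EAIC/EBIC the usual AIC/BIC); the `convention` field
#' labels which construction was used.
#'
#' @param fit A `"curefrail"` fit (either route).
#' @param max_draws Cap on posterior draws used for `dbar` (default 4000,
#'   evenly thinned) — a runtime control, not a statistical one.
#' @return An object of class `"ic_report"`: list with `dic`, `eaic`, `ebic`,
#'   `dbar`, `pd`, `n_params`, `n_obs`, `convention`.
#' @export
information_criteria <- function(fit, max_draws = 4000) {
  stopifnot(inherits(fit, "curefrail"))
  fr <- fit$frame
  p <- fit$n_params; n <- fit$n
  if (inherits(fit, "curefrail_bayes")) {
    draws <- fit$draws
    if (nrow(draws) < 100L)
      stop("chain too short for information criteria (need >= 100 draws)",
           call. = FALSE)
    if (nrow(draws) > max_draws)
      draws <- draws[round(seq(1, nrow(draws), length.out = max_draws)), ,
                     drop = FALSE]
    dev <- -2 * apply(draws, 1, frame_loglik, fr = fr, frailty = fit$frailty)
    dbar <- mean(dev)
    dhat <- -2 * frame_loglik(colMeans(fit$draws), fr, fit$frailty)
    pd <- dbar - dhat
    convention <- "posterior mean deviance (Spiegelhalter pd)"
  } else {
    dbar <- deviance(fit)
    pd <- 0
    convention <- "plug-in at the MLE (pd = 0)"
  }
  structure(list(dic = dbar + pd, eaic = dbar + 2 * p,
                 ebic = dbar + p * log(n), dbar = dbar, pd = pd,
                 n_params = p, n_obs = n, convention = convention),
            class = "ic_report")
}

#' @export
print.ic_report <- function(x, digits = 2, ...) {
  cat(sprintf("DIC %.2f  EAIC %.2f  EBIC %.2f  (dbar %.2f, pd %.2f, p = %d, n = %d)\n",
              x$dic, x$eaic, x$ebic, x$dbar, x$pd, x$n_params, x$n_obs))
  cat("convention:", x$convention, "\n")
  invisible(x)
}

#' Side-by-side criterion comparison of fitted models
#'
#' Produces the familiar criteria-by-model comparison table (rows DIC, EAIC,
#' EBIC) for any set of fits, e.g. a classical and a Bayesian fit of the same
#' model, or frailty vs no-frailty fits.
#'
#' @param ... Named `"curefrail"` fits or `"ic_report"` objects.
#' @return A data.frame with one column per model.
#' @export
compare_ic <- function(...) {
  fits <- list(...)
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- paste0("model", seq_along(fits))
  reports <- lapply(fits, function(f)
    if (inherits(f, "ic_report")) f else information_criteria(f))
  out <- data.frame(row.names = c("DIC", "EAIC", "EBIC"))
  for (nm in names(reports))
    out[[nm]] <- c(reports[[nm]]$dic, reports[[nm]]$eaic, reports[[nm]]$ebic)
  out
}
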