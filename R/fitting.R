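#' Fit a parametric survival law to individual patient data
#'
#' Maximum-likelihood fit with right censoring handled in the likelihood
#' (via [flexsurv::flexsurvreg()]), reported in the `(scale, shape)`
#' parameterisation of [surv_params()].
#'
#' @param records data frame with columns `time` (months) and `event`
#'   (1 = event, 0 = censored), as produced by [simulate_ipd()] or
#'   [reconstruct_ipd()].
#' @param family distribution family, see [surv_params()].
#' @return A `fit_report`: list with elements `params` (a [surv_params()]),
#'   `loglik`, `aic` (`2k - 2 loglik`), `bic` (`k log n - 2 loglik`), `n`,
#'   and `k` (number of free parameters).
#' @export
fit_parametric <- function(records, family = "loglogistic") {
  records <- validate_ipd(records)
  if (nrow(records) < 10L)
    stop("at least 10 records are required to fit", call. = FALSE)
  if (sum(records$event) < 1L)
    stop("non-identifiable: no events in the data", call. = FALSE)
  dist <- switch(family,
    exponential = "exp", weibull = "weibull", lognormal = "lnorm",
    loglogistic = "llogis", gompertz = "gompertz", gengamma = "gengamma",
    stop("unknown family '", family, "'", call. = FALSE))
  fit <- tryCatch(
    flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1,
                          data = records, dist = dist),
    error = function(e) stop("fit failure for family '", family, "': ",
                             conditionMessage(e), call. = FALSE))
  est <- stats::setNames(fit$res[, "est"], rownames(fit$res))
  params <- switch(family,
    exponential = surv_params("exponential", scale = est[["rate"]]),
    weibull     = surv_params("weibull", scale = 1 / est[["scale"]],
                              shape = est[["shape"]]),
    lognormal   = surv_params("lognormal", scale = exp(-est[["meanlog"]]),
                              shape = 1 / est[["sdlog"]]),
    loglogistic = surv_params("loglogistic", scale = 1 / est[["scale"]],
                              shape = est[["shape"]]),
    gompertz    = surv_params("gompertz", scale = est[["rate"]],
                              shape = est[["shape"]]),
    gengamma    = surv_params("gengamma", scale = exp(-est[["mu"]]),
                              shape = 1 / est[["sigma"]], shape2 = est[["Q"]]))
  k <- fit$npars
  n <- nrow(records)
  ll <- fit$loglik
  structure(list(params = params, loglik = ll,
                 aic = 2 * k - 2 * ll, bic = k * log(n) - 2 * ll,
                 n = n, k = k),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("<fit_report> %s  loglik = %.3f  AIC = %.2f  BIC = %.2f  n = %d\n",
              x$params$family, x$loglik, x$aic, x$bic, x$n))
  invisible(x)
}

#' Fit several families and keep all reports
#'
#' @param records as in [fit_parametric()].
#' @param families character vector of families to fit; families whose fit
#'   fails to converge are dropped with a warning.
#' @return list of `fit_report`s.
#' @export
fit_families <- function(records,
                         families = c("exponential", "weibull", "lognormal",
                                      "loglogistic", "gompertz", "gengamma")) {
  out <- list()
  for (f in families) {
    r <- tryCatch(fit_parametric(records, f), error = function(e) {
      warning("family '", f, "' dropped: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(r)) out[[f]] <- r
  }
  out
}

#' Select the best-fitting report
#'
#' Minimal AIC; ties broken by minimal BIC, then by fewest parameters.
#'
#' @param reports list of `fit_report`s.
#' @return the selected `fit_report`.
#' @export
select_best <- function(reports) {
  if (length(reports) == 0L)
    stop("empty collection of fit reports", call. = FALSE)
  aic <- vapply(reports, `[[`, numeric(1), "aic")
  bic <- vapply(reports, `[[`, numeric(1), "bic")
  k <- vapply(reports, `[[`, numeric(1), "k")
  ord <- order(aic, bic, k)
  reports[[ord[1L]]]
}
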