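#' Parametric survival law
#'
#' Container for a parametric survival distribution in the `(scale, shape)`
#' parameterisation used throughout the model.  Time is measured in months.
#' For the log-logistic family the survival function is
#' \deqn{S(t) = (1 + (\lambda t)^{\gamma})^{-1}}
#' so that the median survival is \eqn{1/\lambda}.  Analogous conventions are
#' used for the other families (see Details).
#'
#' @details Families and their survival functions (`l` = scale, `g` = shape):
#' * `exponential`: \eqn{e^{-\lambda t}} (shape unused)
#' * `weibull`: \eqn{e^{-(\lambda t)^\gamma}}
#' * `loglogistic`: \eqn{(1+(\lambda t)^\gamma)^{-1}}
#' * `lognormal`: \eqn{1-\Phi((\log t + \log\lambda)\gamma)}; the median is
#'   again \eqn{1/\lambda} and \eqn{\gamma = 1/\mathrm{sdlog}}
#' * `gompertz`: shape \eqn{\gamma}, rate \eqn{\lambda} as in
#'   [flexsurv::pgompertz()]
#' * `gengamma`: \eqn{\mu = -\log\lambda}, \eqn{\sigma = 1/\gamma}, plus a
#'   third parameter `shape2` (Q), as in [flexsurv::pgengamma()]
#'
#' @param family one of `"exponential"`, `"weibull"`, `"lognormal"`,
#'   `"loglogistic"`, `"gompertz"`, `"gengamma"`.
#' @param scale positive scale parameter (per month).
#' @param shape positive shape parameter; ignored for `exponential`.
#' @param shape2 second shape parameter (generalized gamma only).
#' @return An object of class `surv_params`.
#' @examples
#' p <- surv_params("loglogistic", scale = 0.1524227, shape = 2.850079)
#' survival_at(p, 12)
#' median_survival(p)
#' @export
surv_params <- function(family = c("loglogistic", "exponential", "weibull",
                                   "lognormal", "gompertz", "gengamma"),
                        scale, shape = NULL, shape2 = NULL) {
  family <- match.arg(family)
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop("`scale` must be a single positive number", call. = FALSE)
  if (family != "exponential") {
    if (is.null(shape) || !is.finite(shape) || shape <= 0)
      stop("`shape` must be a single positive number for family '", family, "'",
           call. = FALSE)
  } else shape <- NA_real_
  if (family == "gengamma" && is.null(shape2))
    stop("`shape2` (Q) is required for the generalized gamma family", call. = FALSE)
  structure(list(family = family, scale = scale, shape = shape,
                 shape2 = shape2),
            class = "surv_params")
}

#' @export
print.surv_params <- function(x, ...) {
  cat(sprintf("<surv_params> %s  scale = %g  shape = %s%s\n", x$family,
              x$scale, format(x$shape),
              if (!is.null(x$shape2)) sprintf("  shape2 = %g", x$shape2) else ""))
  invisible(x)
}

#' Hazard ratio with confidence interval
#'
#' @param point hazard-ratio point estimate (> 0).
#' @param ci_low,ci_high bounds of the 95% confidence interval.
#' @return An object of class `hazard_ratio`.
#' @export
hazard_ratio <- function(point, ci_low = point, ci_high = point) {
  if (!is.finite(point) || point <= 0)
    stop("hazard ratio must be positive", call. = FALSE)
  if (!(ci_low <= point && point <= ci_high) || ci_low <= 0)
    stop("hazard-ratio CI must satisfy 0 < ci_low <= point <= ci_high",
         call. = FALSE)
  structure(list(point = point, ci_low = ci_low, ci_high = ci_high),
            class = "hazard_ratio")
}

#' Evaluate a survival function
#'
#' `survival_at(x, t)` returns \eqn{S(t)} for a `surv_params` law or an
#' `hr_curve` (hazard-ratio-adjusted curve).  Values are probabilities in
#' \[0, 1\], non-increasing in `t`, with \eqn{S(0)=1}.
#'
#' @param x a `surv_params` or `hr_curve` object.
#' @param t vector of non-negative times (months).
#' @return numeric vector of survival probabilities.
#' @export
survival_at <- function(x, t) UseMethod("survival_at")

#' @export
survival_at.surv_params <- function(x, t) {
  if (any(!is.finite(t)) || any(t < 0))
    stop("`t` must be finite and non-negative", call. = FALSE)
  l <- x$scale; g <- x$shape
  switch(x$family,
    exponential = exp(-l * t),
    weibull     = exp(-(l * t)^g),
    loglogistic = 1 / (1 + (l * t)^g),
    lognormal   = stats::plnorm(t, meanlog = -log(l), sdlog = 1 / g,
                                lower.tail = FALSE),
    gompertz    = flexsurv::pgompertz(t, shape = g, rate = l,
                                      lower.tail = FALSE),
    gengamma    = flexsurv::pgengamma(t, mu = -log(l), sigma = 1 / g,
                                      Q = x$shape2, lower.tail = FALSE))
}

#' @export
survival_at.hr_curve <- function(x, t) survival_at(x$base, t)^x$hr

#' Median survival time
#'
#' The time `m` at which \eqn{S(m) = 0.5}.  Closed form (\eqn{1/\lambda}) for
#' log-logistic and lognormal; numerical inversion otherwise.
#'
#' @param x a `surv_params` or `hr_curve` object.
#' @return median survival in months.
#' @export
median_survival <- function(x) UseMethod("median_survival")

#' @export
median_survival.surv_params <- function(x) {
  switch(x$family,
    loglogistic = 1 / x$scale,
    lognormal   = 1 / x$scale,
    exponential = log(2) / x$scale,
    weibull     = log(2)^(1 / x$shape) / x$scale,
    .median_numeric(x))
}

#' @export
median_survival.hr_curve <- function(x) .median_numeric(x)

.median_numeric <- function(x) {
  f <- function(t) survival_at(x, t) - 0.5
  upper <- 1
  while (f(upper) > 0 && upper < 1e8) upper <- upper * 2
  stats::uniroot(f, c(0, upper), tol = 1e-12)$root
}

#' Random event times from a survival law
#'
#' Inverse-transform sampling; used by the pseudo-IPD generator.
#'
#' @param n number of draws.
#' @param x a `surv_params` or `hr_curve` object.
#' @return vector of event times (months).
#' @export
rsurv <- function(n, x) {
  u <- stats::runif(n)
  qsurv(x, u)
}

# quantile of the time-to-event law at survival probability u (S(t) = u)
qsurv <- function(x, u) UseMethod("qsurv")

#' @export
qsurv.surv_params <- function(x, u) {
  l <- x$scale; g <- x$shape
  switch(x$family,
    exponential = -log(u) / l,
    weibull     = (-log(u))^(1 / g) / l,
    loglogistic = ((1 - u) / u)^(1 / g) / l,
    lognormal   = stats::qlnorm(u, meanlog = -log(l), sdlog = 1 / g,
                                lower.tail = FALSE),
    gompertz    = flexsurv::qgompertz(u, shape = g, rate = l,
                                      lower.tail = FALSE),
    gengamma    = flexsurv::qgengamma(u, mu = -log(l), sigma = 1 / g,
                                      Q = x$shape2, lower.tail = FALSE))
}

#' @export
qsurv.hr_curve <- function(x, u) qsurv(x$base, u^(1 / x$hr))

#' Apply a hazard ratio to a baseline survival law
#'
#' Under proportional hazards \eqn{S_{new}(t) = S_{base}(t)^{HR}}.  This is
#' the operational rule used to construct the combination-arm curves from the
#' lenvatinib-arm fits, as is standard when only a hazard ratio is reported.
#'
#' @param base a `surv_params` or `hr_curve` object.
#' @param hr a `hazard_ratio`, or a single positive number.
#' @return an object of class `hr_curve` supporting [survival_at()],
#'   [median_survival()] and [rsurv()].
#' @examples
#' os <- surv_params("loglogistic", 0.08526536, 2.926645)
#' survival_at(apply_hr(os, 0.45), 12)
#' @export
apply_hr <- function(base, hr) {
  if (inherits(hr, "hazard_ratio")) hr <- hr$point
  if (!is.finite(hr) || hr <= 0)
    stop("hazard ratio must be positive", call. = FALSE)
  stopifnot(inherits(base, "surv_params") || inherits(base, "hr_curve"))
  if (inherits(base, "hr_curve"))
    return(structure(list(base = base$base, hr = base$hr * hr),
                     class = "hr_curve"))
  structure(list(base = base, hr = hr), class = "hr_curve")
}
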