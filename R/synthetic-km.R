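#' Simulate pseudo individual-patient data
#'
#' Draws event times from a parametric survival law and applies
#' administrative right-censoring at a fixed follow-up cut-off, optionally
#' with uniform staggered accrual (which shortens individual follow-up).
#' This stands in for trial data so the curve-fitting stage is testable.
#'
#' @param params a [surv_params()] or [apply_hr()] curve.
#' @param n number of patients (>= 1).
#' @param censor_time administrative censoring time in months (> 0; may be
#'   `Inf` for no censoring).
#' @param seed integer seed; the output is reproducible given the seed.
#' @param arm strategy label stored in the `arm` column.
#' @param accrual_months accrual window; each patient's follow-up is
#'   `censor_time - U(0, accrual_months)`.  Default 0 (single cut-off).
#' @return data frame with columns `time`, `event` (1 = event, 0 = censored)
#'   and `arm`.
#' @examples
#' pfs <- surv_params("loglogistic", 0.1524227, 2.850079)
#' ipd <- simulate_ipd(pfs, n = 170, censor_time = 25, seed = 1)
#' @export
simulate_ipd <- function(params, n, censor_time = 25, seed = NULL,
                         arm = "lenvatinib", accrual_months = 0) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("`n` must be a positive count", call. = FALSE)
  if (!is.numeric(censor_time) || censor_time <= 0)
    stop("`censor_time` must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  t <- rsurv(n, params)
  fu <- rep(censor_time, n)
  if (accrual_months > 0)
    fu <- pmax(censor_time - stats::runif(n, 0, accrual_months), 1e-9)
  event <- as.integer(t <= fu)
  data.frame(time = pmin(t, fu), event = event, arm = arm,
             stringsAsFactors = FALSE)
}

validate_ipd <- function(records) {
  if (is.null(records) || NROW(records) == 0L)
    stop("empty collection of records", call. = FALSE)
  records <- as.data.frame(records)
  if (!all(c("time", "event") %in% names(records)))
    stop("records need `time` and `event` columns", call. = FALSE)
  if (any(!is.finite(records$time)) || any(records$time < 0))
    stop("times must be finite and non-negative", call. = FALSE)
  if (!all(records$event %in% c(0L, 1L)))
    stop("`event` must be 0 or 1", call. = FALSE)
  records
}

#' Kaplan-Meier estimate with a landmark risk table
#'
#' Product-limit estimator (via [survival::survfit()]) plus a numbers-at-risk
#' table at regular landmark times, mimicking published trial curves.
#'
#' @param records data frame with `time` and `event` columns.
#' @param landmark_every spacing of the risk-table landmarks, months.
#' @return object of class `km_curve`: list with `times` (starting at 0),
#'   `survival` (starting at 1), and `risk_table` (data frame `time`,
#'   `n_risk`).
#' @export
km_estimate <- function(records, landmark_every = 3) {
  records <- validate_ipd(records)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  times <- c(0, fit$time)
  surv <- c(1, fit$surv)
  landmarks <- seq(0, max(records$time), by = landmark_every)
  n_risk <- vapply(landmarks, function(tt) sum(records$time >= tt), numeric(1))
  structure(list(times = times, survival = surv,
                 risk_table = data.frame(time = landmarks, n_risk = n_risk)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> %d coordinates, final S = %.3f at t = %.2f\n",
              length(x$times), x$survival[length(x$survival)],
              x$times[length(x$times)]))
  invisible(x)
}

#' Construct a km_curve from digitized coordinates
#'
#' @param times,survival digitized curve coordinates (months, probabilities).
#' @param risk_table optional data frame with columns `time`, `n_risk`.
#' @return a `km_curve`.
#' @export
km_curve <- function(times, survival, risk_table = NULL) {
  if (length(times) != length(survival))
    stop("`times` and `survival` must have equal length", call. = FALSE)
  o <- order(times)
  times <- times[o]; survival <- survival[o]
  if (times[1] > 0) { times <- c(0, times); survival <- c(1, survival) }
  if (any(survival < 0 | survival > 1))
    stop("survival probabilities must lie in [0, 1]", call. = FALSE)
  if (any(diff(survival) > 1e-9))
    stop("survival must be non-increasing", call. = FALSE)
  if (abs(survival[1] - 1) > 1e-9)
    stop("survival must equal 1 at time 0", call. = FALSE)
  if (!is.null(risk_table)) {
    if (any(diff(risk_table$n_risk) > 0))
      stop("numbers at risk must be non-increasing", call. = FALSE)
  }
  structure(list(times = times, survival = survival, risk_table = risk_table),
            class = "km_curve")
}

#' Reconstruct pseudo individual-patient data from a Kaplan-Meier curve
#'
#' Interval-allocation algorithm in the spirit of published IPD-reconstruction
#' methods: within each risk-table interval, events are allocated at the curve
#' coordinates so that the rebuilt product-limit estimate matches the input
#' survival, and the at-risk deficit not explained by events is assigned as
#' censoring at the interval end.  Without a risk table, no censoring before
#' the last coordinate is assumed (flagged in the `risk_table_used`
#' attribute).
#'
#' @param curve a `km_curve`.
#' @param n_total total number of patients to reconstruct.
#' @param arm strategy label for the output records.
#' @return data frame of records (`time`, `event`, `arm`) with attribute
#'   `risk_table_used`.
#' @export
reconstruct_ipd <- function(curve, n_total, arm = "reconstructed") {
  stopifnot(inherits(curve, "km_curve"))
  steps <- which(diff(curve$survival) < 0) + 1L  # indices of drops
  if (n_total < length(steps))
    stop("`n_total` must be at least the number of distinct event times",
         call. = FALSE)
  rt <- curve$risk_table
  use_rt <- !is.null(rt) && nrow(rt) >= 2L
  if (use_rt && any(diff(rt$n_risk) > 0))
    stop("inconsistent risk table: numbers at risk increase", call. = FALSE)

  times <- curve$times; surv <- curve$survival
  out_t <- numeric(0); out_e <- integer(0)

  if (!use_rt) {
    # no censoring before the last coordinate: events in proportion to drops
    at_risk <- n_total; s_cur <- 1
    for (i in steps) {
      d <- round(at_risk * (1 - surv[i] / s_cur))
      d <- max(0L, min(at_risk, d))
      if (d > 0) { out_t <- c(out_t, rep(times[i], d)); out_e <- c(out_e, rep(1L, d)) }
      s_cur <- s_cur * (1 - d / at_risk)
      at_risk <- at_risk - d
    }
    if (at_risk > 0) {
      out_t <- c(out_t, rep(times[length(times)], at_risk))
      out_e <- c(out_e, rep(0L, at_risk))
    }
  } else {
    # scale the risk table to n_total
    scale <- n_total / rt$n_risk[1]
    lm_t <- rt$time
    lm_n <- round(rt$n_risk * scale)
    lm_n[1] <- n_total
    at_risk <- n_total; s_cur <- 1
    for (j in seq_len(length(lm_t))) {
      t0 <- lm_t[j]
      t1 <- if (j < length(lm_t)) lm_t[j + 1] else Inf
      in_iv <- steps[times[steps] > t0 & times[steps] <= t1]
      for (i in in_iv) {
        if (at_risk <= 0) break
        d <- round(at_risk * (1 - surv[i] / s_cur))
        d <- max(0L, min(at_risk, d))
        if (d > 0) { out_t <- c(out_t, rep(times[i], d)); out_e <- c(out_e, rep(1L, d)) }
        s_cur <- s_cur * (1 - d / at_risk)
        at_risk <- at_risk - d
      }
      if (j < length(lm_t)) {
        cens <- at_risk - lm_n[j + 1]
        if (cens > 0) {
          out_t <- c(out_t, rep(t1, cens)); out_e <- c(out_e, rep(0L, cens))
          at_risk <- at_risk - cens
        }
      } else if (at_risk > 0) {
        end_t <- max(times[length(times)], t0)
        out_t <- c(out_t, rep(end_t, at_risk)); out_e <- c(out_e, rep(0L, at_risk))
        at_risk <- 0
      }
    }
  }
  out <- data.frame(time = out_t, event = out_e, arm = arm,
                    stringsAsFactors = FALSE)
  attr(out, "risk_table_used") <- use_rt
  out
}

#' Write / read IPD and KM curves as delimited text
#'
#' @param records,path,curve arguments for the respective reader/writer.
#' @return `read_ipd` returns a records data frame; `read_km_curve` a
#'   `km_curve`; the writers return the path invisibly.
#' @name km_io
NULL

#' @rdname km_io
#' @export
write_ipd <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname km_io
#' @export
read_ipd <- function(path) {
  validate_ipd(utils::read.delim(path))
}

#' @rdname km_io
#' @param risk_path optional path of the separate risk-table file.
#' @export
write_km_curve <- function(curve, path, risk_path = NULL) {
  utils::write.table(data.frame(time = curve$times, survival = curve$survival),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(risk_path) && !is.null(curve$risk_table))
    utils::write.table(curve$risk_table, risk_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname km_io
#' @export
read_km_curve <- function(path, risk_path = NULL) {
  d <- utils::read.delim(path)
  rt <- if (!is.null(risk_path)) utils::read.delim(risk_path) else NULL
  km_curve(d$time, d$survival, rt)
}
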