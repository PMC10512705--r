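#' Uncertain-parameter specification
#'
#' One row of the sensitivity-analysis parameter table: the configuration
#' key the parameter binds to, its base value and range, and the sampling
#' distribution used in the probabilistic analysis.
#'
#' @param name display name.
#' @param key dotted configuration key (see [modify_config()]).
#' @param base,low,high base value and range (low <= base <= high).
#' @param dist one of `"beta"`, `"gamma"`, `"lognormal"`,
#'   `"lognormal_truncated"` (survival scale/shape) or `"fixed"`.
#' @return object of class `param_spec`.
#' @export
param_spec <- function(name, key, base, low = base, high = base,
                       dist = c("fixed", "beta", "gamma", "lognormal",
                                "lognormal_truncated")) {
  dist <- match.arg(dist)
  if (!(low <= base && base <= high))
    stop("need low <= base <= high for '", name, "'", call. = FALSE)
  structure(list(name = name, key = key, base = base, low = low, high = high,
                 dist = dist), class = "param_spec")
}

#' Default parameter table for sensitivity analyses
#'
#' All uncertain inputs with their ranges and distributions: beta for
#' probabilities, incidences and utilities; gamma for unit costs; log-normal
#' for hazard ratios (hyper-parameters from the confidence interval);
#' truncated log-scale normal for the survival scale/shape parameters; the
#' discount rate varies 0-8% in the one-way analysis and is fixed in the
#' probabilistic analysis.  Ranges without published data are +/-20% of the
#' base value.
#'
#' @param config configuration supplying the base values.
#' @return list of [param_spec()]s.
#' @export
default_param_specs <- function(config = default_config()) {
  cs <- config$costs
  pm20 <- function(x) c(low = 0.8 * x, high = 1.2 * x)
  sp <- list()
  add <- function(sp, name, key, base, low, high, dist) {
    sp[[length(sp) + 1L]] <- param_spec(name, key, base, low, high, dist)
    sp
  }
  # survival parameters (+/-20%, truncated log-normal)
  sp <- add(sp, "PFS scale (lambda)", "pfs.scale", config$pfs$scale,
            0.121938, 0.182907, "lognormal_truncated")
  sp <- add(sp, "PFS shape (gamma)", "pfs.shape", config$pfs$shape,
            2.2800632, 3.4200948, "lognormal_truncated")
  sp <- add(sp, "OS scale (lambda)", "os.scale", config$os$scale,
            0.068212, 0.102318, "lognormal_truncated")
  sp <- add(sp, "OS shape (gamma)", "os.shape", config$os$shape,
            2.341316, 3.511974, "lognormal_truncated")
  # hazard ratios
  sp <- add(sp, "HR for PFS", "hr_pfs.point", config$hr_pfs$point,
            config$hr_pfs$low, config$hr_pfs$high, "lognormal")
  sp <- add(sp, "HR for OS", "hr_os.point", config$hr_os$point,
            config$hr_os$low, config$hr_os$high, "lognormal")
  # adverse-event incidences, both arms
  ae_rng <- list(
    tacelen = list(hyperbilirubinemia = c(0.075, 0.113),
                   alt_ast = c(0.325, 0.487),
                   weight_decreased = c(0.061, 0.091),
                   hypertension = c(0.165, 0.247),
                   diarrhea = c(0.042, 0.064)),
    lenvatinib = list(hyperbilirubinemia = c(0.024, 0.036),
                      alt_ast = c(0.024, 0.036),
                      weight_decreased = c(0.057, 0.085),
                      hypertension = c(0.157, 0.235),
                      diarrhea = c(0.034, 0.050)))
  for (arm in names(ae_rng)) for (ae in names(ae_rng[[arm]])) {
    key <- paste("ae_incidence", arm, ae, sep = ".")
    sp <- add(sp, sprintf("%s incidence (%s)", ae, arm), key,
              config$ae_incidence[[arm]][[ae]],
              ae_rng[[arm]][[ae]][1], ae_rng[[arm]][[ae]][2], "beta")
  }
  # costs
  cost_rng <- list(
    c("Cost of hyperbilirubinemia", "costs.ae.hyperbilirubinemia", 124.90, 99.92, 149.88),
    c("Cost of ALT/AST elevation", "costs.ae.alt_ast", 45.60, 36.48, 54.72),
    c("Cost of weight decreased", "costs.ae.weight_decreased", 75.20, 60.16, 90.24),
    c("Cost of hypertension", "costs.ae.hypertension", 1.48, 1.18, 1.78),
    c("Cost of diarrhea", "costs.ae.diarrhea", 3.61, 2.89, 4.33),
    c("Cost of hepatectomy", "costs.hepatectomy", 9058.24, 7246.59, 10869.89),
    c("Cost of hospitalization per cycle", "costs.hospitalization_cycle", 384.00, 307.20, 460.80),
    c("Cost of TACE per cycle", "costs.tace_cycle", 1929.00, 1543.20, 2314.80),
    c("Cost of BSC per cycle", "costs.bsc_cycle", 363.00, 290.40, 435.60),
    c("Cost of test per cycle", "costs.test_cycle", 359.96, 287.97, 431.95),
    c("Cost of end-of-life care", "costs.end_of_life", 2176.00, 1740.80, 2611.20),
    c("Cost of lenvatinib per cycle", "costs.lenvatinib_cycle", 1054.88, 843.90, 1265.86))
  for (r in cost_rng)
    sp <- add(sp, r[1], r[2], as.numeric(r[3]), as.numeric(r[4]),
              as.numeric(r[5]), "gamma")
  # utilities
  sp <- add(sp, "Utility of PFS", "utilities.pfs", config$utilities$pfs,
            0.608, 0.912, "beta")
  sp <- add(sp, "Utility of PD", "utilities.pd", config$utilities$pd,
            0.544, 0.816, "beta")
  sp <- add(sp, "Utility of RFS", "utilities.rfs", config$utilities$rfs,
            0.608, 0.912, "beta")
  # discount rate: one-way 0-8%, fixed in PSA
  sp <- add(sp, "Discount rate", "discount_rate", config$discount_rate,
            0, 0.08, "fixed")
  # proportions
  sp <- add(sp, "Proportion hepatectomy after TACE-LEN",
            "hepatectomy_fraction.tacelen",
            config$hepatectomy_fraction$tacelen, 0.122, 0.184, "beta")
  sp <- add(sp, "Proportion hepatectomy after lenvatinib",
            "hepatectomy_fraction.lenvatinib",
            config$hepatectomy_fraction$lenvatinib, 0.014, 0.022, "beta")
  sp <- add(sp, "5-year recurrence after hepatectomy", "recurrence_5yr",
            config$recurrence_5yr, 0.15, 0.20, "beta")
  names(sp) <- vapply(sp, `[[`, character(1), "name")
  sp
}

icer_under <- function(config) {
  suppressWarnings(run_base_case(config))$icer
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-evaluates the incremental cost-effectiveness ratio with each parameter
#' at its low and high bound, all others at base, and ranks parameters by
#' the width of the resulting ICER excursion.
#'
#' @param config base configuration.
#' @param specs list of [param_spec()]s.
#' @return data frame `name`, `low`, `high`, `icer_low`, `icer_high`,
#'   `span`, sorted by decreasing span; attribute `icer_base`.
#' @export
tornado <- function(config = default_config(),
                    specs = default_param_specs(config)) {
  base_icer <- icer_under(config)
  rows <- lapply(specs, function(s) {
    il <- icer_under(modify_config(config, structure(list(s$low), names = s$key)))
    ih <- icer_under(modify_config(config, structure(list(s$high), names = s$key)))
    data.frame(name = s$name, low = s$low, high = s$high,
               icer_low = il, icer_high = ih, span = abs(ih - il),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$span), ]
  rownames(out) <- NULL
  attr(out, "icer_base") <- base_icer
  attr(out, "config_hash") <- config_hash(config)
  out
}

# distribution hyper-parameters from base value and range: the range is
# treated as a 95% interval, SD = (high - low) / (2 * 1.96)
psa_hyper <- function(s) {
  sd <- (s$high - s$low) / (2 * stats::qnorm(0.975))
  if (sd == 0) return(list(dist = "fixed"))  # degenerate range
  switch(s$dist,
    beta = {
      m <- s$base
      if (sd^2 >= m * (1 - m)) return(list(dist = "uniform"))
      v <- m * (1 - m) / sd^2 - 1
      list(dist = "beta", shape1 = m * v, shape2 = (1 - m) * v)
    },
    gamma = {
      m <- s$base
      list(dist = "gamma", shape = m^2 / sd^2, rate = m / sd^2)
    },
    lognormal = {
      list(dist = "lognormal", meanlog = log(s$base),
           sdlog = (log(s$high) - log(s$low)) / (2 * stats::qnorm(0.975)))
    },
    lognormal_truncated = {
      list(dist = "lognormal_truncated", meanlog = log(s$base),
           sdlog = (log(s$high) - log(s$low)) / (2 * stats::qnorm(0.975)),
           low = s$low, high = s$high)
    },
    fixed = list(dist = "fixed"))
}

#' Draw one joint parameter vector for the probabilistic analysis
#'
#' Beta and gamma hyper-parameters by method of moments with
#' `SD = (high - low) / (2 * 1.96)`; hazard ratios log-normal with
#' `mu = log(point)` and `sigma` from the CI width; survival scale/shape
#' log-scale normal truncated to the range (inverse-CDF truncation, so draws
#' are reproducible); `fixed` parameters stay at base.  If the beta moments
#' are infeasible the draw falls back to uniform on the range with a
#' warning.
#'
#' @param specs list of [param_spec()]s.
#' @param seed optional seed (set once before repeated calls for a
#'   reproducible stream).
#' @return named numeric vector, one value per spec.
#' @export
draw_params <- function(specs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(specs, function(s) {
    h <- psa_hyper(s)
    switch(h$dist,
      fixed = s$base,
      uniform = {
        warning("beta moments infeasible for '", s$name,
                "': falling back to uniform", call. = FALSE)
        stats::runif(1, s$low, s$high)
      },
      beta = stats::rbeta(1, h$shape1, h$shape2),
      gamma = stats::rgamma(1, shape = h$shape, rate = h$rate),
      lognormal = stats::rlnorm(1, h$meanlog, h$sdlog),
      lognormal_truncated = {
        if (h$sdlog == 0) return(s$base)
        pl <- stats::pnorm(log(h$low), h$meanlog, h$sdlog)
        ph <- stats::pnorm(log(h$high), h$meanlog, h$sdlog)
        exp(stats::qnorm(stats::runif(1, pl, ph), h$meanlog, h$sdlog))
      })
  }, numeric(1))
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo simulation: `n_reps` joint draws of all uncertain parameters,
#' a full two-strategy model evaluation per draw, and the
#' cost-effectiveness acceptability curve (fraction of draws with positive
#' incremental net monetary benefit) over a willingness-to-pay grid.
#'
#' @param config base configuration.
#' @param specs list of [param_spec()]s.
#' @param n_reps number of replications.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param wtp_grid willingness-to-pay grid for the acceptability curve.
#' @return list with `samples` (data frame: draw index, incremental cost and
#'   QALYs, ICER, NMB at the configured threshold), `ceac` (data frame
#'   `wtp`, `probability`), `n_failed`, and the mean incremental results.
#' @export
run_psa <- function(config = default_config(),
                    specs = default_param_specs(config),
                    n_reps = 1000, seed = 1,
                    wtp_grid = seq(0, 60000, by = 500)) {
  if (n_reps < 1) stop("`n_reps` must be at least 1", call. = FALSE)
  set.seed(seed)
  draws <- matrix(NA_real_, n_reps, length(specs),
                  dimnames = list(NULL, names(specs)))
  for (i in seq_len(n_reps)) draws[i, ] <- draw_params(specs)
  keys <- vapply(specs, `[[`, character(1), "key")

  dc <- dq <- rep(NA_real_, n_reps)
  failed <- 0L
  for (i in seq_len(n_reps)) {
    cfg <- config
    for (j in seq_along(keys))
      cfg <- set_config_key(cfg, keys[j], draws[i, j])
    res <- tryCatch(suppressWarnings(run_base_case(cfg)),
                    error = function(e) NULL)
    if (is.null(res)) { failed <- failed + 1L; next }
    dc[i] <- res$inc_cost; dq[i] <- res$inc_qaly
  }
  ok <- !is.na(dc)
  ceac <- data.frame(
    wtp = wtp_grid,
    probability = vapply(wtp_grid,
                         function(w) mean(w * dq[ok] - dc[ok] > 0),
                         numeric(1)))
  samples <- data.frame(draw = seq_len(n_reps), inc_cost = dc, inc_qaly = dq,
                        icer = ifelse(dq > 0, dc / dq, NA_real_),
                        nmb = config$wtp * dq - dc)
  structure(list(samples = samples, draws = draws, ceac = ceac,
                 n_failed = failed,
                 mean_inc_cost = mean(dc[ok]), mean_inc_qaly = mean(dq[ok]),
                 acceptability_at_wtp = mean(config$wtp * dq[ok] - dc[ok] > 0),
                 config_hash = config_hash(config), seed = seed),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d draws (%d failed)  mean dCost $%.0f  mean dQALY %.3f\n",
              nrow(x$samples), x$n_failed, x$mean_inc_cost, x$mean_inc_qaly))
  cat(sprintf("  acceptability at configured WTP: %.1f%%\n",
              100 * x$acceptability_at_wtp))
  invisible(x)
}

#' Willingness-to-pay threshold at a target acceptability
#'
#' Linear interpolation of the cost-effectiveness acceptability curve at the
#' target probability (default 50%).
#'
#' @param ceac data frame `wtp`, `probability` (as in [run_psa()]).
#' @param target target probability.
#' @return willingness-to-pay value, USD/QALY.
#' @export
wtp_crossing <- function(ceac, target = 0.5) {
  p <- ceac$probability; w <- ceac$wtp
  if (all(p < target) || all(p > target))
    stop("target probability outside the range of the acceptability curve",
         call. = FALSE)
  above <- which(p >= target)
  i <- above[1]
  if (i == 1L) return(w[1])
  p0 <- p[i - 1]; p1 <- p[i]
  if (p1 == p0) return(w[i])
  w[i - 1] + (target - p0) / (p1 - p0) * (w[i] - w[i - 1])
}
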