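#' Discount factor
#'
#' Continuous-time compound discounting `1 / (1 + r)^t`.
#'
#' @param t time in years (vectorised).
#' @param r annual discount rate.
#' @return multiplier in (0, 1].
#' @export
discount_factor <- function(t, r) {
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  if (r < 0) stop("`r` must be non-negative", call. = FALSE)
  1 / (1 + r)^t
}

#' Economic inputs of one strategy
#'
#' Extracts unit costs, utilities, discount rate, adverse-event incidences
#' and exposure rules from the configuration.  The lenvatinib drug cost
#' scales linearly with the configured daily dose (12 mg reference).
#'
#' @param config a [default_config()] configuration.
#' @param strategy `"tacelen"` or `"lenvatinib"`.
#' @return object of class `economic_inputs`.
#' @export
economic_inputs <- function(config = default_config(),
                            strategy = c("tacelen", "lenvatinib")) {
  strategy <- match.arg(strategy)
  cs <- config$costs
  ae_inc <- config$ae_incidence[[strategy]]
  if (is.null(ae_inc))
    stop("no adverse-event incidences configured for strategy '", strategy,
         "'", call. = FALSE)
  ae_cost <- cs$ae
  common <- intersect(names(ae_inc), names(ae_cost))
  structure(list(
    strategy = strategy,
    lenvatinib_cycle = cs$lenvatinib_cycle * config$lenvatinib_dose / 12,
    tace_cycle = if (strategy == "tacelen") cs$tace_cycle else 0,
    tace_sessions = if (strategy == "tacelen") config$tace_sessions else 0,
    hospitalization_cycle = cs$hospitalization_cycle,
    test_cycle = cs$test_cycle,
    bsc_cycle = cs$bsc_cycle * config$bsc_coverage,
    hepatectomy = cs$hepatectomy,
    end_of_life = cs$end_of_life,
    ae_lump = sum(unlist(ae_inc[common]) * unlist(ae_cost[common])),
    utilities = unlist(config$utilities[c("pfs", "rfs", "pd")]),
    discount_rate = config$discount_rate,
    days_per_year = config$days_per_year,
    cycle_days = config$cycle_days,
    test_in_pd = isTRUE(config$test_in_pd),
    hosp_in_pd = isTRUE(config$hosp_in_pd),
    half_cycle_correction = isTRUE(config$half_cycle_correction)
  ), class = "economic_inputs")
}

#' Accumulate discounted costs, life years and QALYs over a trace
#'
#' State costs per cycle: lenvatinib + hospitalization + tests while
#' progression-free (plus TACE for the first `tace_sessions` cycles of the
#' combination arm); hospitalization + tests while recurrence-free; best
#' supportive care (optionally still with tests and hospitalization) after
#' progression.  One-time costs: hepatectomy on each PFS->RFS entry,
#' end-of-life care on each death entry, and an incidence-weighted
#' adverse-event lump at cycle 0.  Life years weight the alive occupancy by
#' the cycle length; QALYs weight each state by its utility.  Everything is
#' discounted at the annual rate with per-cycle exponent
#' `t = cycle * cycle_days / days_per_year` (occupancy taken at cycle start;
#' with `half_cycle_correction` the mean of start and end occupancy is used).
#'
#' @param trace a [run_cohort()] trace.
#' @param econ an [economic_inputs()].
#' @return list with `cost`, `ly`, `qaly` (discounted), their undiscounted
#'   counterparts, and a per-component cost breakdown.
#' @export
accumulate <- function(trace, econ) {
  stopifnot(inherits(trace, "markov_trace"), inherits(econ, "economic_inputs"))
  if (econ$strategy != attr(trace, "strategy"))
    stop("trace strategy '", attr(trace, "strategy"),
         "' does not match economic inputs for '", econ$strategy, "'",
         call. = FALSE)
  n <- nrow(trace)
  dyr <- econ$cycle_days / econ$days_per_year
  t_yr <- trace$cycle * dyr
  occ <- as.matrix(trace[, c("pfs", "rfs", "pd")])
  if (econ$half_cycle_correction) {
    # average of the occupancy at the start of this cycle and the next
    occ_use <- (occ + rbind(occ[-1, , drop = FALSE],
                            occ[n, , drop = FALSE])) / 2
    t_use <- (trace$cycle + 0.5) * dyr
  } else {
    occ_use <- occ
    t_use <- t_yr
  }
  disc <- discount_factor(t_use, econ$discount_rate)

  alive <- rowSums(occ_use)
  ly <- sum(disc * alive * dyr)
  ly_undisc <- sum(alive * dyr)
  u <- econ$utilities
  qualw <- occ_use %*% u[c("pfs", "rfs", "pd")]
  qaly <- sum(disc * qualw * dyr)
  qaly_undisc <- sum(qualw * dyr)

  pd_cycle_cost <- econ$bsc_cycle +
    (if (econ$test_in_pd) econ$test_cycle else 0) +
    (if (econ$hosp_in_pd) econ$hospitalization_cycle else 0)
  comp <- c(
    lenvatinib = sum(disc * occ_use[, "pfs"] * econ$lenvatinib_cycle),
    tace = if (econ$tace_sessions > 0) {
      idx <- seq_len(min(ceiling(econ$tace_sessions), n))
      sum(disc[idx] * occ_use[idx, "pfs"] * econ$tace_cycle)
    } else 0,
    pfs_care = sum(disc * occ_use[, "pfs"] *
                     (econ$hospitalization_cycle + econ$test_cycle)),
    rfs_care = sum(disc * occ_use[, "rfs"] *
                     (econ$hospitalization_cycle + econ$test_cycle)),
    pd_care = sum(disc * occ_use[, "pd"] * pd_cycle_cost),
    hepatectomy = sum(disc * trace$entry_rfs * econ$hepatectomy),
    end_of_life = sum(disc * trace$entry_death * econ$end_of_life),
    ae = econ$ae_lump)
  list(cost = sum(comp), ly = ly, qaly = qaly,
       cost_undiscounted = NA_real_, ly_undiscounted = ly_undisc,
       qaly_undiscounted = qaly_undisc, components = comp)
}

#' Evaluate one strategy end to end
#'
#' @param config a configuration.
#' @param strategy `"tacelen"` or `"lenvatinib"`.
#' @return list with the trace and the accumulated `cost`, `ly`, `qaly`.
#' @export
run_strategy <- function(config = default_config(),
                         strategy = c("tacelen", "lenvatinib")) {
  strategy <- match.arg(strategy)
  trace <- run_cohort(transition_inputs(config, strategy))
  res <- accumulate(trace, economic_inputs(config, strategy))
  c(list(strategy = strategy, trace = trace), res)
}

#' Cost-effectiveness comparison of the two strategies
#'
#' @param tacelen,lenvatinib per-strategy results (lists with `cost`, `ly`,
#'   `qaly`), e.g. from [run_strategy()].
#' @param wtp willingness-to-pay threshold, USD/QALY.
#' @return object of class `cea_result` with per-strategy values,
#'   incremental cost/LY/QALY, ICER per QALY and per LY, net monetary
#'   benefit at `wtp`, and a `verdict` (`"cost-effective"`,
#'   `"not cost-effective"`, `"dominant"` or `"dominated"`).
#' @export
compute_cea <- function(tacelen, lenvatinib, wtp = 38201) {
  dc <- tacelen$cost - lenvatinib$cost
  dly <- tacelen$ly - lenvatinib$ly
  dq <- tacelen$qaly - lenvatinib$qaly
  icer <- if (dq > 0) dc / dq else NA_real_
  icer_ly <- if (dly > 0) dc / dly else NA_real_
  nmb <- wtp * dq - dc
  verdict <- if (dq > 0 && dc <= 0) "dominant"
    else if (dq <= 0 && dc >= 0 && !(dq == 0 && dc == 0)) "dominated"
    else if (dq == 0 && dc == 0) "equivalent"
    else if (!is.na(icer) && icer <= wtp) "cost-effective"
    else "not cost-effective"
  structure(list(
    tacelen = tacelen[c("cost", "ly", "qaly")],
    lenvatinib = lenvatinib[c("cost", "ly", "qaly")],
    inc_cost = dc, inc_ly = dly, inc_qaly = dq,
    icer = icer, icer_per_ly = icer_ly, nmb = nmb, wtp = wtp,
    verdict = verdict), class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  usd <- function(v) formatC(v, format = "f", digits = 2, big.mark = ",")
  cat("Cost-effectiveness results (discounted)\n")
  cat(sprintf("  %-12s cost $%s  LY %.3f  QALY %.3f\n", "TACE-LEN",
              usd(x$tacelen$cost), x$tacelen$ly, x$tacelen$qaly))
  cat(sprintf("  %-12s cost $%s  LY %.3f  QALY %.3f\n", "lenvatinib",
              usd(x$lenvatinib$cost), x$lenvatinib$ly, x$lenvatinib$qaly))
  cat(sprintf("  incremental  cost $%s  LY %.3f  QALY %.3f\n",
              usd(x$inc_cost), x$inc_ly, x$inc_qaly))
  if (!is.na(x$icer))
    cat(sprintf("  ICER $%s/QALY ($%s/LY)\n", usd(x$icer),
                usd(x$icer_per_ly)))
  cat(sprintf("  NMB at WTP $%s/QALY: $%s  ->  %s\n",
              formatC(x$wtp, format = "d", big.mark = ","), usd(x$nmb),
              x$verdict))
  invisible(x)
}

#' Run the base-case analysis
#'
#' Evaluates both strategies under the configuration and compares them at
#' the configured willingness-to-pay threshold.
#'
#' @param config a configuration.
#' @return a `cea_result` with the per-strategy traces attached as the
#'   `runs` attribute.
#' @examples
#' \donttest{
#' res <- run_base_case()
#' res$icer
#' }
#' @export
run_base_case <- function(config = default_config()) {
  tl <- run_strategy(config, "tacelen")
  len <- run_strategy(config, "lenvatinib")
  out <- compute_cea(tl, len, wtp = config$wtp)
  attr(out, "runs") <- list(tacelen = tl, lenvatinib = len)
  out
}
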