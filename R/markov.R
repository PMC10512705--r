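#' Convert a probability between time periods
#'
#' Converts a probability over period `from` into the equivalent probability
#' over period `to` under a constant hazard: `1 - (1 - p)^(to/from)`.
#'
#' @param p probability in \[0, 1).
#' @param from period over which `p` applies.
#' @param to target period (same units as `from`).
#' @return probability over the target period.
#' @examples
#' prob_convert(0.0074, from = 365.25, to = 21)  # annual -> per 21-day cycle
#' @export
prob_convert <- function(p, from, to) {
  if (any(p < 0) || any(p > 1)) stop("`p` must be in [0, 1]", call. = FALSE)
  if (from <= 0 || to <= 0) stop("periods must be positive", call. = FALSE)
  if (any(p == 1) && to < from)
    stop("undefined rate: p = 1 cannot be shortened", call. = FALSE)
  1 - (1 - p)^(to / from)
}

#' Per-cycle transition probability from a survival curve
#'
#' Conditional event probability over one cycle:
#' `1 - S(t + delta) / S(t)` with `t = cycle * delta`.
#'
#' @param curve a [surv_params()] or [apply_hr()] curve.
#' @param cycle 0-based cycle index (vectorised).
#' @param delta cycle length in months.
#' @return probability in \[0, 1\].
#' @export
cycle_transition_prob <- function(curve, cycle, delta) {
  t0 <- cycle * delta
  s0 <- survival_at(curve, t0)
  if (any(s0 <= 0))
    stop("absorbing state: survival is 0 at the cycle start", call. = FALSE)
  pmin(pmax(1 - survival_at(curve, t0 + delta) / s0, 0), 1)
}

#' Transition inputs of one strategy
#'
#' Bundles everything the cohort engine needs: the two survival curves, the
#' natural-mortality and recurrence probabilities, the hepatectomy
#' (down-staging) fraction, and cycle/horizon settings taken from the
#' configuration.
#'
#' @param config a [default_config()] style configuration.
#' @param strategy `"tacelen"` or `"lenvatinib"`.
#' @return object of class `transition_inputs`.
#' @export
transition_inputs <- function(config = default_config(),
                              strategy = c("tacelen", "lenvatinib")) {
  strategy <- match.arg(strategy)
  curves <- strategy_curves(config, strategy)
  delta_months <- config$cycle_days / config$days_per_month
  p_nat <- prob_convert(config$natural_mortality_annual,
                        from = config$days_per_year, to = config$cycle_days)
  p_nat_pfs <- prob_convert(
    min(config$natural_mortality_annual * config$pfs_death_multiplier, 1),
    from = config$days_per_year, to = config$cycle_days)
  p_rec <- prob_convert(config$recurrence_5yr,
                        from = 5 * config$days_per_year, to = config$cycle_days)
  structure(list(
    strategy = strategy,
    pfs_curve = curves$pfs, os_curve = curves$os,
    delta_months = delta_months,
    p_death_pfs = p_nat_pfs,
    p_death_rfs = if (isTRUE(config$natural_mortality_in_rfs)) p_nat else 0,
    p_recurrence = p_rec,
    hepatectomy_fraction = config$hepatectomy_fraction[[strategy]],
    hepatectomy_window_months = config$hepatectomy_window_months,
    max_cycles = as.integer(config$max_cycles),
    death_stop = config$death_stop,
    pd_death_mode = config$pd_death_mode
  ), class = "transition_inputs")
}

# number of cycles in the hepatectomy window
hep_window_cycles <- function(inputs) {
  sum((seq_len(inputs$max_cycles) - 1) * inputs$delta_months <
        inputs$hepatectomy_window_months)
}

#' Per-cycle transition-probability matrix
#'
#' Row/column order `PFS, RFS, PD, DEATH`; each row sums to one.  PFS exits
#' are allocated to RFS (hepatectomy), PD (progression along the PFS curve)
#' and DEATH (natural mortality); RFS exits to PD (recurrence) and DEATH
#' (natural mortality); PD exits to DEATH only; DEATH is absorbing and no
#' transition re-enters an earlier state.
#'
#' @param inputs a [transition_inputs()].
#' @param cycle 0-based cycle index.
#' @param hep_prob per-cycle PFS->RFS probability inside the hepatectomy
#'   window (see [calibrate_hepatectomy()]).
#' @param pd_death override for the PD->DEATH probability; default derives it
#'   from the OS curve.
#' @return 4x4 matrix.
#' @export
build_transition_matrix <- function(inputs, cycle, hep_prob = 0,
                                    pd_death = NULL) {
  d <- inputs$delta_months
  q_prog <- cycle_transition_prob(inputs$pfs_curve, cycle, d)
  if (is.null(pd_death))
    pd_death <- cycle_transition_prob(inputs$os_curve, cycle, d)
  h <- if (cycle * d < inputs$hepatectomy_window_months) hep_prob else 0
  p_stay_pfs <- 1 - q_prog - inputs$p_death_pfs - h
  if (p_stay_pfs < 0)
    stop("infeasible parameters: PFS exit probabilities exceed 1 at cycle ",
         cycle, call. = FALSE)
  p_stay_rfs <- 1 - inputs$p_recurrence - inputs$p_death_rfs
  if (p_stay_rfs < 0)
    stop("infeasible parameters: RFS exit probabilities exceed 1",
         call. = FALSE)
  m <- rbind(
    c(p_stay_pfs, h, q_prog, inputs$p_death_pfs),
    c(0, p_stay_rfs, inputs$p_recurrence, inputs$p_death_rfs),
    c(0, 0, 1 - pd_death, pd_death),
    c(0, 0, 0, 1))
  dimnames(m) <- list(c("PFS", "RFS", "PD", "DEATH"),
                      c("PFS", "RFS", "PD", "DEATH"))
  m
}

# cumulative PFS->RFS entries for a constant in-window hepatectomy
# probability h; only the window cycles matter, so the recursion is short
hep_entries <- function(inputs, h, q_prog, n_window) {
  pfs <- 1; entered <- 0
  for (k in seq_len(n_window)) {
    entered <- entered + pfs * h
    pfs <- pfs * (1 - q_prog[k] - inputs$p_death_pfs - h)
    if (pfs < 0) return(Inf)  # infeasible h
  }
  entered
}

#' Calibrate the per-cycle hepatectomy probability
#'
#' Finds, by bisection, the constant per-cycle PFS->RFS probability over the
#' first `hepatectomy_window_months` such that cumulative RFS entries equal
#' the target fraction ever undergoing down-staging hepatectomy.
#'
#' @param inputs a [transition_inputs()].
#' @return per-cycle probability.
#' @export
calibrate_hepatectomy <- function(inputs) {
  target <- inputs$hepatectomy_fraction
  if (target <= 0) return(0)
  n_window <- hep_window_cycles(inputs)
  q_prog <- cycle_transition_prob(inputs$pfs_curve, seq_len(n_window) - 1,
                                  inputs$delta_months)
  lo <- 0; hi <- 0.9
  if (hep_entries(inputs, hi, q_prog, n_window) < target)
    stop("infeasible parameters: hepatectomy fraction unreachable within ",
         "the surgery window", call. = FALSE)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    e <- hep_entries(inputs, mid, q_prog, n_window)
    if (is.infinite(e) || e > target) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Run the cohort through the Markov model
#'
#' The whole cohort starts in PFS.  Each cycle, progression follows the
#' conditional probability of the strategy's PFS curve, down-staged patients
#' move to RFS during the surgery window, recurrences move RFS to PD, and
#' deaths occur from PFS/RFS (natural mortality) and PD.  Under the default
#' `pd_death_mode = "os_conditional"`, PD occupants die with the OS curve's
#' conditional per-cycle probability; under `"calibrated"`, the cycle's total
#' death increment implied by the OS curve is assigned to PD after
#' subtracting natural-mortality deaths (floored at zero), which forces the
#' cohort's overall survival to track the OS curve.  The run stops once the
#' death occupancy reaches `death_stop` or at `max_cycles`.
#'
#' @param inputs a [transition_inputs()].
#' @return object of class `markov_trace`: data frame with `cycle`,
#'   `time_months`, occupancies `pfs`, `rfs`, `pd`, `death` (at cycle start),
#'   and incident transitions during the cycle (`entry_rfs`, `entry_pd`,
#'   `entry_death`).  Attribute `hepatectomy_prob` carries the calibrated
#'   per-cycle surgery probability.
#' @export
run_cohort <- function(inputs) {
  stopifnot(inherits(inputs, "transition_inputs"))
  n <- inputs$max_cycles
  d <- inputs$delta_months
  cycles <- 0:(n - 1)
  q_prog <- cycle_transition_prob(inputs$pfs_curve, cycles, d)
  q_os <- cycle_transition_prob(inputs$os_curve, cycles, d)
  h <- calibrate_hepatectomy(inputs)
  n_window <- hep_window_cycles(inputs)

  occ <- matrix(0, n, 4, dimnames = list(NULL, c("pfs", "rfs", "pd", "death")))
  inc <- matrix(0, n, 3, dimnames = list(NULL, c("entry_rfs", "entry_pd",
                                                 "entry_death")))
  s <- c(1, 0, 0, 0)
  used <- n
  for (k in seq_len(n)) {
    occ[k, ] <- s
    hh <- if (k <= n_window) h else 0
    if (inputs$pd_death_mode == "calibrated") {
      alive <- s[1] + s[2] + s[3]
      nat <- s[1] * inputs$p_death_pfs + s[2] * inputs$p_death_rfs
      q_pd <- if (s[3] > 1e-12) min(1, max(0, (alive * q_os[k] - nat) / s[3])) else 0
    } else q_pd <- q_os[k]
    stay_pfs <- 1 - q_prog[k] - inputs$p_death_pfs - hh
    if (stay_pfs < 0)
      stop("infeasible parameters: PFS exit probabilities exceed 1 at cycle ",
           k - 1, call. = FALSE)
    new_rfs_entries <- s[1] * hh
    new_pd_entries <- s[1] * q_prog[k] + s[2] * inputs$p_recurrence
    new_deaths <- s[1] * inputs$p_death_pfs + s[2] * inputs$p_death_rfs +
      s[3] * q_pd
    s <- c(s[1] * stay_pfs,
           s[2] * (1 - inputs$p_recurrence - inputs$p_death_rfs) + new_rfs_entries,
           s[3] * (1 - q_pd) + new_pd_entries,
           s[4] + new_deaths)
    inc[k, ] <- c(new_rfs_entries, new_pd_entries, new_deaths)
    if (s[4] >= inputs$death_stop) { used <- k; break }
  }
  if (s[4] < inputs$death_stop)
    warning(sprintf("cohort not %.0f%% dead at the %d-cycle cap (death occupancy %.4f)",
                    100 * inputs$death_stop, n, s[4]), call. = FALSE)
  keep <- seq_len(used)
  tr <- data.frame(cycle = cycles[keep], time_months = cycles[keep] * d,
                   occ[keep, , drop = FALSE], inc[keep, , drop = FALSE])
  structure(tr, class = c("markov_trace", "data.frame"),
            delta_months = d, strategy = inputs$strategy,
            hepatectomy_prob = h, final_death = s[4])
}

#' Export a trace as delimited text
#' @param trace a `markov_trace`.
#' @param path output file.
#' @export
write_trace <- function(trace, path) {
  utils::write.table(as.data.frame(trace), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
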