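#' Subgroup hazard-ratio table
#'
#' The 24 patient subgroups of the LAUNCH trial with their progression-free
#' and overall-survival hazard ratios (TACE-LEN vs lenvatinib) and 95%
#' confidence intervals, as used for the subgroup analyses.
#'
#' @return data frame with columns `group`, `label`, `hr_pfs`, `hr_pfs_low`,
#'   `hr_pfs_high`, `hr_os`, `hr_os_low`, `hr_os_high`.
#' @export
subgroup_specs <- function() {
  g <- function(group, label, p, pl, ph, o, ol, oh)
    data.frame(group = group, label = label, hr_pfs = p, hr_pfs_low = pl,
               hr_pfs_high = ph, hr_os = o, hr_os_low = ol, hr_os_high = oh,
               stringsAsFactors = FALSE)
  rbind(
    g("Age", "60 and younger",      0.37, 0.27, 0.50, 0.42, 0.29, 0.61),
    g("Age", "older than 60",       0.55, 0.35, 0.84, 0.52, 0.30, 0.89),
    g("Sex", "Male",                0.43, 0.33, 0.56, 0.43, 0.31, 0.60),
    g("Sex", "Female",              0.46, 0.27, 0.80, 0.52, 0.27, 1.00),
    g("Bodyweight", "<60 kg",       0.42, 0.28, 0.64, 0.46, 0.28, 0.76),
    g("Bodyweight", ">=60 kg",      0.44, 0.32, 0.59, 0.43, 0.30, 0.63),
    g("Aetiology", "HBV",           0.43, 0.33, 0.56, 0.47, 0.34, 0.64),
    g("Aetiology", "Others",        0.44, 0.22, 0.89, 0.34, 0.15, 0.78),
    g("ECOG-PS", "0",               0.46, 0.33, 0.64, 0.40, 0.26, 0.62),
    g("ECOG-PS", "1",               0.33, 0.22, 0.48, 0.45, 0.29, 0.70),
    g("AFP", "<400 ng/mL",          0.53, 0.38, 0.75, 0.50, 0.33, 0.77),
    g("AFP", ">=400 ng/mL",         0.35, 0.25, 0.51, 0.39, 0.26, 0.61),
    g("ALBI grade", "Grade 1",      0.36, 0.22, 0.58, 0.47, 0.27, 0.82),
    g("ALBI grade", "Grade 2",      0.46, 0.34, 0.61, 0.44, 0.31, 0.63),
    g("No. of tumors", "Single",    0.44, 0.25, 0.76, 0.55, 0.27, 1.11),
    g("No. of tumors", "Multiple",  0.44, 0.34, 0.58, 0.43, 0.31, 0.60),
    g("Main tumor size", "<5 cm",   0.46, 0.29, 0.73, 0.38, 0.20, 0.71),
    g("Main tumor size", ">=5 cm",  0.42, 0.32, 0.56, 0.47, 0.33, 0.66),
    g("Primary tumor", "Yes",       0.44, 0.34, 0.57, 0.44, 0.32, 0.61),
    g("Primary tumor", "No",        0.37, 0.16, 0.86, 0.30, 0.07, 1.34),
    g("PVTT", "Yes",                0.31, 0.23, 0.41, 0.34, 0.24, 0.49),
    g("PVTT", "No",                 0.67, 0.43, 1.05, 0.72, 0.40, 1.29),
    g("EHS", "Yes",                 0.46, 0.33, 0.63, 0.56, 0.38, 0.82),
    g("EHS", "No",                  0.40, 0.28, 0.59, 0.32, 0.19, 0.52)
  )
}

subgroup_config <- function(config, row) {
  modify_config(config,
    "hr_pfs.point" = row$hr_pfs, "hr_pfs.low" = row$hr_pfs_low,
    "hr_pfs.high" = row$hr_pfs_high,
    "hr_os.point" = row$hr_os, "hr_os.low" = row$hr_os_low,
    "hr_os.high" = row$hr_os_high)
}

#' Subgroup analyses
#'
#' Replaces the overall hazard ratios with each subgroup's PFS and OS hazard
#' ratios, keeps every other parameter at its overall-population value, and
#' reruns the base case (and optionally the probabilistic analysis, from
#' which the acceptability at the configured willingness-to-pay is taken).
#'
#' @param config base configuration (never modified).
#' @param specs subgroup table as from [subgroup_specs()].
#' @param with_psa also run a probabilistic analysis per subgroup.
#' @param n_reps,seed probabilistic-analysis settings.
#' @return data frame `group`, `label`, HRs, `icer`, and `acceptability`
#'   (NA unless `with_psa`).
#' @export
run_subgroups <- function(config = default_config(), specs = subgroup_specs(),
                          with_psa = FALSE, n_reps = 1000, seed = 1) {
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    row <- specs[i, ]
    cfg <- subgroup_config(config, row)
    icer <- icer_under(cfg)
    acc <- NA_real_
    if (with_psa) {
      psa <- run_psa(cfg, default_param_specs(cfg), n_reps = n_reps,
                     seed = seed)
      acc <- psa$acceptability_at_wtp
    }
    data.frame(group = row$group, label = row$label,
               hr_pfs = row$hr_pfs, hr_os = row$hr_os,
               icer = icer, acceptability = acc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "config_hash") <- config_hash(config)
  out
}

#' Scenario specifications
#'
#' The five scenario analyses: (1) 5-year post-hepatectomy recurrence 15% or
#' 20%; (2) fixed time horizons of 3, 5 or 7 years (52, 87 or 122 cycles of
#' 21 days, overriding the mortality stopping rule); (3) only 80% or 50% of
#' progressed patients receiving best supportive care (cost side only);
#' (4) lenvatinib daily dose 8 or 10 mg (drug cost scaled by dose);
#' (5) direct death probability from the progression-free state at 2 or 4
#' times the natural mortality rate.
#'
#' @return named list of override lists (dotted keys as in
#'   [modify_config()]).
#' @export
scenario_specs <- function() {
  list(
    "Recurrence of HCC = 0.15" = list("recurrence_5yr" = 0.15),
    "Recurrence of HCC = 0.20" = list("recurrence_5yr" = 0.20),
    "Model runtime (year) = 3" = list("max_cycles" = 52L, "death_stop" = 1),
    "Model runtime (year) = 5" = list("max_cycles" = 87L, "death_stop" = 1),
    "Model runtime (year) = 7" = list("max_cycles" = 122L, "death_stop" = 1),
    "80% of patients receive BSC" = list("bsc_coverage" = 0.8),
    "50% of patients receive BSC" = list("bsc_coverage" = 0.5),
    "Daily dose of lenvatinib (mg) = 8" = list("lenvatinib_dose" = 8),
    "Daily dose of lenvatinib (mg) = 10" = list("lenvatinib_dose" = 10),
    "Direct death from PFS = 14.8 per 1000" = list("pfs_death_multiplier" = 2),
    "Direct death from PFS = 29.6 per 1000" = list("pfs_death_multiplier" = 4))
}

#' Scenario analyses
#'
#' One full two-strategy evaluation per scenario, applying only the stated
#' overrides to the base configuration (which is never modified).
#'
#' @param config base configuration.
#' @param specs named list of override lists, as [scenario_specs()].
#' @return data frame `scenario`, `cost_tacelen`, `cost_lenvatinib`,
#'   `qaly_tacelen`, `qaly_lenvatinib`, `icer`.
#' @export
run_scenarios <- function(config = default_config(),
                          specs = scenario_specs()) {
  rows <- lapply(names(specs), function(nm) {
    cfg <- modify_config(config, specs[[nm]])
    res <- suppressWarnings(run_base_case(cfg))
    data.frame(scenario = nm,
               cost_tacelen = res$tacelen$cost,
               cost_lenvatinib = res$lenvatinib$cost,
               qaly_tacelen = res$tacelen$qaly,
               qaly_lenvatinib = res$lenvatinib$qaly,
               icer = res$icer, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "config_hash") <- config_hash(config)
  out
}
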