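# shared fixtures: the printed survival laws and a quiet base-case runner

pfs_len <- surv_params("loglogistic", scale = 0.1524227, shape = 2.850079)
os_len <- surv_params("loglogistic", scale = 0.08526536, shape = 2.926645)

quiet_base_case <- function(config = default_config()) {
  suppressWarnings(run_base_case(config))
}

quiet_cohort <- function(inputs) suppressWarnings(run_cohort(inputs))

# a hand-built trace frozen in PFS for n cycles (for economics oracles)
frozen_pfs_trace <- function(n_cycles, config = default_config(),
                             strategy = "lenvatinib") {
  d <- config$cycle_days / config$days_per_month
  tr <- data.frame(cycle = 0:(n_cycles - 1),
                   time_months = (0:(n_cycles - 1)) * d,
                   pfs = 1, rfs = 0, pd = 0, death = 0,
                   entry_rfs = 0, entry_pd = 0, entry_death = 0)
  structure(tr, class = c("markov_trace", "data.frame"),
            delta_months = d, strategy = strategy, hepatectomy_prob = 0,
            final_death = 0)
}
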