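test_that("probability-period conversion has its closed-form values", {
  # annual natural mortality 7.4 per mille -> per 21-day cycle
  expect_equal(prob_convert(0.0074, from = 365.25, to = 21),
               0.0004269528609, tolerance = 1e-9)
  # 5-year recurrence of 19% -> per cycle
  expect_equal(prob_convert(0.19, from = 5 * 365.25, to = 21),
               0.002420142236, tolerance = 1e-9)
  # identity and composition consistency
  expect_equal(prob_convert(0.3, 10, 10), 0.3)
  expect_equal(prob_convert(prob_convert(0.3, 12, 1), 1, 12), 0.3,
               tolerance = 1e-12)
  expect_error(prob_convert(1, from = 12, to = 1), "undefined")
})

test_that("per-cycle transition probabilities follow the curve", {
  d <- 21 / 30.4375
  # memoryless law: identical conditional probability every cycle
  ex <- surv_params("exponential", 0.12)
  q <- cycle_transition_prob(ex, 0:50, d)
  expect_equal(q, rep(1 - exp(-0.12 * d), 51), tolerance = 1e-12)
  # zero-length cycle -> zero probability
  expect_equal(cycle_transition_prob(pfs_len, 0:5, 0), rep(0, 6))
  # first cycle of the printed PFS law, from the closed form
  expect_equal(cycle_transition_prob(pfs_len, 0, d), 0.001627482208,
               tolerance = 1e-9)
})

test_that("transition matrices are proper and honour the state diagram", {
  inputs <- transition_inputs(default_config(), "tacelen")
  h <- calibrate_hepatectomy(inputs)
  for (k in c(0, 1, 5, 50, 150, 199)) {
    m <- build_transition_matrix(inputs, k, hep_prob = h)
    expect_equal(rowSums(m), c(PFS = 1, RFS = 1, PD = 1, DEATH = 1),
                 tolerance = 1e-12)
    expect_true(all(m >= 0))
    expect_equal(unname(m[, "PFS"]), c(m[1, 1], 0, 0, 0))  # no return to PFS
    expect_equal(unname(m[4, ]), c(0, 0, 0, 1))            # death absorbing
  }
  # surgery pathway switched off: no transition into RFS
  len_in <- transition_inputs(default_config(), "lenvatinib")
  m0 <- build_transition_matrix(len_in, 0, hep_prob = 0)
  expect_identical(unname(m0[, "RFS"]), c(0, 1 - len_in$p_recurrence -
                                            len_in$p_death_rfs, 0, 0))
})

test_that("the cohort trace conserves occupancy with monotone death", {
  for (arm in c("tacelen", "lenvatinib")) {
    tr <- quiet_cohort(transition_inputs(default_config(), arm))
    occ <- tr$pfs + tr$rfs + tr$pd + tr$death
    expect_lt(max(abs(occ - 1)), 1e-9)
    expect_true(all(diff(tr$death) >= -1e-15))
    expect_true(all(as.matrix(tr[, c("pfs", "rfs", "pd", "death")]) >= 0))
    expect_equal(unlist(tr[1, c("pfs", "rfs", "pd", "death")]),
                 c(pfs = 1, rfs = 0, pd = 0, death = 0))
  }
})

test_that("a hazard-free cohort never leaves the initial state", {
  cfg <- modify_config(default_config(),
    "natural_mortality_annual" = 0, "recurrence_5yr" = 0,
    "hepatectomy_fraction.lenvatinib" = 0,
    "pfs.scale" = 1e-9, "os.scale" = 1e-9, "max_cycles" = 40L)
  tr <- quiet_cohort(transition_inputs(cfg, "lenvatinib"))
  expect_true(all(abs(tr$pfs - 1) < 1e-9))
  expect_true(all(tr$death < 1e-9))
})

test_that("the hepatectomy calibration hits the printed fractions", {
  for (arm in c("tacelen", "lenvatinib")) {
    target <- default_config()$hepatectomy_fraction[[arm]]
    tr <- quiet_cohort(transition_inputs(default_config(), arm))
    expect_equal(sum(tr$entry_rfs), target, tolerance = 1e-8)
    # surgery only happens inside the 6-month window
    expect_true(all(tr$entry_rfs[tr$time_months >= 6] == 0))
  }
})

test_that("calibrated death mode makes cohort survival track the OS curve", {
  cfg <- modify_config(default_config(), "pd_death_mode" = "calibrated")
  # lenvatinib arm: model survival vs the extrapolated OS law
  tr <- quiet_cohort(transition_inputs(cfg, "lenvatinib"))
  sos <- survival_at(os_len, tr$time_months)
  m36 <- tr$time_months <= 36
  expect_lt(max(abs((1 - tr$death) - sos)[m36]), 0.03)
  # combination arm against the HR-adjusted curve
  tr2 <- quiet_cohort(transition_inputs(cfg, "tacelen"))
  sos2 <- survival_at(apply_hr(os_len, 0.45), tr2$time_months)
  expect_lt(max(abs((1 - tr2$death) - sos2)[tr2$time_months <= 36]), 0.03)
  # life expectancy approximates the area under the OS curve (the floor on
  # unassignable deaths leaves a small positive bias)
  dyr <- 21 / 365.25
  lyu <- sum((tr$pfs + tr$rfs + tr$pd) * dyr)
  auc <- integrate(function(t) survival_at(os_len, t), 0,
                   max(tr$time_months) + 21 / 30.4375)$value / 12
  expect_equal(lyu, auc, tolerance = 0.1)
})

test_that("neutral hazard ratios collapse the arms onto each other", {
  cfg <- modify_config(default_config(),
    "hr_pfs.point" = 1, "hr_os.point" = 1,
    "hepatectomy_fraction.tacelen" = default_config()$hepatectomy_fraction$lenvatinib)
  tl <- quiet_cohort(transition_inputs(cfg, "tacelen"))
  len <- quiet_cohort(transition_inputs(cfg, "lenvatinib"))
  expect_equal(tl$pfs, len$pfs, tolerance = 1e-12)
  expect_equal(tl$death, len$death, tolerance = 1e-12)
})
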