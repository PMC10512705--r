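test_that("degenerate specifications always return the base value", {
  s <- param_spec("fixed thing", "discount_rate", 0.05, 0.05, 0.05, "beta")
  set.seed(1)
  expect_identical(draw_params(list(a = s)), c(a = 0.05))
  sf <- param_spec("fixed", "wtp", 38201, dist = "fixed")
  expect_identical(unname(draw_params(list(sf))), 38201)
})

test_that("beta draws match the method-of-moments target", {
  s <- param_spec("u", "utilities.pfs", 0.76, 0.608, 0.912, "beta")
  set.seed(42)
  x <- replicate(1e5, draw_params(list(s)))
  expect_equal(mean(x), 0.76, tolerance = 0.01)
  expect_equal(sd(x), (0.912 - 0.608) / (2 * qnorm(0.975)), tolerance = 0.01)
  expect_true(all(x > 0 & x < 1))
})

test_that("hazard-ratio draws respect the published interval", {
  s <- param_spec("hr", "hr_pfs.point", 0.43, 0.34, 0.60, "lognormal")
  set.seed(7)
  x <- replicate(1e5, draw_params(list(s)))
  inside <- mean(x >= 0.34 & x <= 0.60)
  expect_gt(inside, 0.93)
  expect_lt(inside, 0.97)
  expect_equal(median(x), 0.43, tolerance = 0.01)
})

test_that("truncated survival-parameter draws stay inside their range", {
  s <- param_spec("lam", "pfs.scale", 0.1524227, 0.121938, 0.182907,
                  "lognormal_truncated")
  set.seed(3)
  x <- replicate(5e3, draw_params(list(s)))
  expect_true(all(x >= 0.121938 & x <= 0.182907))
})

test_that("the tornado ranks spans and flags unknown keys", {
  cfg <- default_config()
  specs <- list(
    u_pd = param_spec("Utility of PD", "utilities.pd", 0.68, 0.544, 0.816, "beta"),
    frozen = param_spec("Frozen cost", "costs.bsc_cycle", 363, 363, 363, "gamma"))
  tab <- tornado(cfg, specs)
  expect_identical(tab$name[nrow(tab)], "Frozen cost")   # zero span ranked last
  expect_equal(tab$span[tab$name == "Frozen cost"], 0)
  expect_gt(tab$span[tab$name == "Utility of PD"], 0)
  bad <- list(param_spec("nope", "not.a.key", 1, 0.5, 1.5, "gamma"))
  expect_error(tornado(cfg, bad), "unknown configuration key")
})

test_that("raising a pure PD cost moves the ICER monotonically", {
  cfg <- default_config()
  icers <- vapply(c(181.5, 363, 726), function(v)
    suppressWarnings(run_base_case(
      modify_config(cfg, "costs.bsc_cycle" = v)))$icer, numeric(1))
  expect_true(all(diff(icers) > 0))
})

test_that("a degenerate PSA collapses to the base case", {
  cfg <- default_config()
  specs <- list(param_spec("fixed util", "utilities.pfs", 0.76, dist = "fixed"))
  psa <- run_psa(cfg, specs, n_reps = 5, seed = 1)
  base <- quiet_base_case(cfg)
  expect_true(all(abs(psa$samples$inc_cost - base$inc_cost) < 1e-9))
  expect_true(all(abs(psa$samples$inc_qaly - base$inc_qaly) < 1e-9))
  # the CEAC is then a step function at the base ICER
  expect_true(all(psa$ceac$probability[psa$ceac$wtp < base$icer] == 0))
  expect_true(all(psa$ceac$probability[psa$ceac$wtp > base$icer] == 1))
  expect_equal(wtp_crossing(psa$ceac, 0.5), base$icer, tolerance = 500)
})

test_that("a fixed seed reproduces the PSA bit for bit", {
  cfg <- default_config()
  specs <- default_param_specs(cfg)
  a <- run_psa(cfg, specs, n_reps = 20, seed = 99)
  b <- run_psa(cfg, specs, n_reps = 20, seed = 99)
  expect_identical(a$samples, b$samples)
  expect_identical(a$ceac, b$ceac)
})

test_that("the acceptability curve has the right limits", {
  cfg <- default_config()
  psa <- run_psa(cfg, n_reps = 100, seed = 12)
  expect_equal(psa$ceac$probability[psa$ceac$wtp == 0], 0)  # always dearer
  dq <- psa$samples$inc_qaly
  expect_equal(psa$ceac$probability[nrow(psa$ceac)], mean(dq > 60000^-1 * psa$samples$inc_cost),
               tolerance = 0.05)
  expect_true(all(diff(psa$ceac$probability) >= -0.05))  # near-monotone
})

test_that("interpolation of the crossing threshold is linear", {
  ceac <- data.frame(wtp = c(30000, 32000), probability = c(0.4, 0.6))
  expect_equal(wtp_crossing(ceac, 0.5), 31000)
  expect_error(wtp_crossing(data.frame(wtp = 1:2, probability = c(0.8, 0.9)),
                            0.5), "outside")
})
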