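test_that("log-logistic survival has its closed-form values", {
  # S(0) = 1 and S(1/lambda) = 0.5 for any shape
  for (g in c(0.5, 1, 2.850079)) {
    p <- surv_params("loglogistic", scale = 0.1524227, shape = g)
    expect_identical(survival_at(p, 0), 1)
    expect_equal(survival_at(p, 1 / 0.1524227), 0.5, tolerance = 1e-12)
  }
  # printed PFS parameters at one year (hand-evaluated closed form)
  expect_equal(survival_at(pfs_len, 12), 0.1517548602, tolerance = 1e-9)
  expect_error(survival_at(pfs_len, -1), "non-negative")
})

test_that("survival curves are bounded and non-increasing", {
  tt <- seq(0, 300, by = 0.25)
  curves <- list(pfs_len, os_len, apply_hr(os_len, 0.45),
                 surv_params("weibull", 0.1, 1.4),
                 surv_params("exponential", 0.2),
                 surv_params("lognormal", 0.1, 2),
                 surv_params("gompertz", 0.05, 0.1))
  for (cv in curves) {
    s <- survival_at(cv, tt)
    expect_true(all(s >= 0 & s <= 1))
    expect_true(all(diff(s) <= 1e-12))
  }
})

test_that("median survival matches the closed form and inverts S", {
  expect_equal(median_survival(pfs_len), 6.560702573, tolerance = 1e-9)
  expect_equal(median_survival(os_len), 11.72809216, tolerance = 1e-9)
  expect_equal(median_survival(surv_params("loglogistic", 1, 2)), 1)
  for (x in list(pfs_len, apply_hr(os_len, 0.45),
                 surv_params("weibull", 0.2, 1.3))) {
    expect_equal(survival_at(x, median_survival(x)), 0.5, tolerance = 1e-9)
  }
})

test_that("hazard-ratio adjustment is the S^HR mapping", {
  # identity at HR = 1
  tt <- seq(0, 60, by = 0.5)
  expect_equal(survival_at(apply_hr(os_len, 1), tt), survival_at(os_len, tt))
  # direct power evaluation at the median of the base curve
  t50 <- median_survival(os_len)
  expect_equal(survival_at(apply_hr(os_len, 0.43), t50), 0.7422617853,
               tolerance = 1e-9)
  # a protective HR lengthens the median
  expect_gt(median_survival(apply_hr(os_len, 0.45)), median_survival(os_len))
  expect_error(apply_hr(os_len, -0.3), "positive")
  expect_error(hazard_ratio(0.43, 0.5, 0.6), "ci_low")
})

test_that("maximum-likelihood refit recovers the generating parameters", {
  ipd <- simulate_ipd(pfs_len, n = 5000, censor_time = 25, seed = 11)
  fit <- fit_parametric(ipd, "loglogistic")
  expect_equal(fit$params$scale, 0.1524227, tolerance = 0.05)
  expect_equal(fit$params$shape, 2.850079, tolerance = 0.05)
  # information-criterion identities hold exactly
  expect_equal(fit$aic, 2 * fit$k - 2 * fit$loglik)
  expect_equal(fit$bic, fit$k * log(fit$n) - 2 * fit$loglik)
  expect_identical(fit$n, 5000L)
})

test_that("model selection prefers the generating family", {
  # exponential data: BIC should favour exponential over log-logistic
  ipd <- simulate_ipd(surv_params("exponential", 0.1), n = 2000,
                      censor_time = 40, seed = 3)
  f_exp <- fit_parametric(ipd, "exponential")
  f_ll <- fit_parametric(ipd, "loglogistic")
  expect_lt(f_exp$bic, f_ll$bic)
  # log-logistic data: the full family scan selects log-logistic
  ipd2 <- simulate_ipd(pfs_len, n = 5000, censor_time = 25, seed = 11)
  best <- select_best(fit_families(ipd2))
  expect_identical(best$params$family, "loglogistic")
})

test_that("select_best breaks ties by AIC, then BIC, then parameter count", {
  r <- function(aic, bic, k)
    structure(list(params = list(family = "x"), loglik = 0, aic = aic,
                   bic = bic, n = 100, k = k), class = "fit_report")
  expect_identical(select_best(list(r(100, 90, 2), r(110, 80, 2)))$aic, 100)
  expect_identical(select_best(list(r(100, 95, 2), r(100, 90, 2)))$bic, 90)
  expect_identical(select_best(list(r(100, 90, 3), r(100, 90, 1)))$k, 1)
  expect_error(select_best(list()), "empty")
})

test_that("degenerate fits signal instead of returning nonsense", {
  all_cens <- data.frame(time = runif(50, 1, 10), event = 0L)
  expect_error(fit_parametric(all_cens, "loglogistic"), "non-identifiable")
  expect_error(fit_parametric(data.frame(time = 1:5, event = 1L)), "at least 10")
})
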