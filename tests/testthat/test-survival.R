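test_that("survival functions take their closed forms and start at 1", {
  curves <- list(
    parametric_survival("exponential", c(rate = 0.1)),
    parametric_survival("weibull", c(shape = 1.7, scale = 12)),
    parametric_survival("gompertz", c(shape = 0.05, rate = 0.02)),
    parametric_survival("loglogistic", c(shape = 2, scale = 9))
  )
  for (cv in curves) {
    expect_identical(survival_at(cv, 0), 1)
    s <- survival_at(cv, seq(0, 300, by = 0.5))
    expect_true(all(s >= 0 & s <= 1))
    expect_true(all(diff(s) <= 0))
  }
  expect_equal(survival_at(curves[[1]], 10), exp(-1))
  expect_equal(survival_at(curves[[2]], 12), exp(-1))
  expect_equal(survival_at(curves[[3]], 20),
               exp(-(0.02 / 0.05) * (exp(0.05 * 20) - 1)))
  expect_equal(survival_at(curves[[4]], 9), 0.5)
  expect_error(survival_at(curves[[1]], -1), "negative")
})

test_that("Weibull with shape 1 coincides with the exponential", {
  wb <- parametric_survival("weibull", c(shape = 1, scale = 10))
  ex <- parametric_survival("exponential", c(rate = 0.1))
  t <- seq(0, 120, by = 1)
  expect_equal(survival_at(wb, t), survival_at(ex, t))
})

test_that("median matches the closed form and a root-finding oracle", {
  wb <- parametric_survival("weibull", c(shape = 2, scale = 12))
  expect_equal(surv_median(wb), 12 * log(2)^(1 / 2), tolerance = 1e-10)
  # independent oracle: numeric root of S(t) = 1/2
  root <- uniroot(function(t) survival_at(wb, t) - 0.5,
                  lower = 0, upper = 100, tol = 1e-12)$root
  expect_equal(surv_median(wb), root, tolerance = 1e-8)
  gz <- parametric_survival("gompertz", c(shape = 0.08, rate = 0.03))
  root_gz <- uniroot(function(t) survival_at(gz, t) - 0.5,
                     lower = 0, upper = 200, tol = 1e-12)$root
  expect_equal(surv_median(gz), root_gz, tolerance = 1e-8)
})

test_that("invalid curve parameters are rejected", {
  expect_error(parametric_survival("weibull", c(shape = -1, scale = 10)),
               "range")
  expect_error(parametric_survival("gompertz", c(shape = -0.1, rate = 0.02)),
               "range")
  expect_error(parametric_survival("weibull", c(shape = 1)), "needs")
})

test_that("proportional-hazards transform behaves as S^HR", {
  os <- parametric_survival("exponential", c(rate = 0.05), "OS")
  t <- seq(0, 240, by = 1)

  # HR = 1 is the identity
  expect_equal(survival_at(apply_hazard_ratio(os, hr_chain(1)), t),
               survival_at(os, t))

  # exponential with HR 2 doubles the rate and halves the median
  os2 <- apply_hazard_ratio(os, hr_chain(2))
  expect_equal(os2$params$rate, 0.10)
  expect_equal(surv_median(os2), surv_median(os) / 2)

  # chain {1.25, 0.80} multiplies to 1 -> identity
  ch <- hr_chain(c(1.25, 0.80))
  expect_equal(combined_hr(ch), prod(c(1.25, 0.80)))
  expect_equal(survival_at(apply_hazard_ratio(os, ch), t),
               survival_at(os, t))

  # Weibull stays in-family with the correct scale transform
  wb <- parametric_survival("weibull", c(shape = 1.4, scale = 11))
  hr <- 1.7
  wb2 <- apply_hazard_ratio(wb, hr_chain(hr))
  expect_s3_class(wb2, "parametric_survival")
  expect_equal(survival_at(wb2, t), survival_at(wb, t)^hr)

  # log-logistic is not closed under PH; generic wrapper still equals S^hr
  ll <- parametric_survival("loglogistic", c(shape = 2, scale = 9))
  ll2 <- apply_hazard_ratio(ll, hr_chain(0.6))
  expect_equal(survival_at(ll2, t), survival_at(ll, t)^0.6)

  expect_error(apply_hazard_ratio(os, -2), "> 0")
  expect_error(hr_chain(c(1, 0)), "> 0")
})

test_that("PH transform preserves monotonicity and endpoints for random HRs", {
  set.seed(11)
  t <- seq(0, 300, by = 1)
  for (i in 1:25) {
    base <- random_curve()
    hr <- exp(rnorm(1, 0, 0.5))
    s <- survival_at(apply_hazard_ratio(base, hr_chain(hr)), t)
    expect_identical(s[1], 1)
    expect_true(all(s >= 0 & s <= 1))
    expect_true(all(diff(s) <= 1e-12))
  }
})

test_that("clamped PFS never exceeds OS", {
  pfs <- parametric_survival("exponential", c(rate = 0.05), "PFS")
  os <- parametric_survival("exponential", c(rate = 0.10), "OS") # crossing
  t <- 0:120
  s <- survival_at(clamp_pfs(pfs, os), t)
  expect_true(all(s <= survival_at(os, t) + 1e-12))
  expect_true(all(diff(s) <= 1e-12))
})

test_that("maximum-likelihood fitting recovers simulation truth", {
  spec <- ipd_sim_spec(1500, "weibull", c(shape = 1.4, scale = 12),
                       censor_fraction = 0.2)
  ipd <- simulate_ipd(spec, seed = 7)
  fit <- fit_parametric(ipd, "weibull", "PFS")
  expect_equal(fit$curve$params$shape, 1.4, tolerance = 0.15)
  expect_equal(fit$curve$params$scale, 12, tolerance = 0.08)
  expect_equal(fit$aic, 2 * 2 - 2 * fit$log_likelihood)
  expect_equal(fit$bic, 2 * log(1500) - 2 * fit$log_likelihood)
  expect_identical(fit$n_events + fit$n_censored, nrow(ipd))

  # repeated fits on the same data are identical (deterministic optimizer)
  fit2 <- fit_parametric(ipd, "weibull", "PFS")
  expect_identical(fit$curve$params, fit2$curve$params)
})

test_that("Weibull fit of exponential data finds shape near 1 (nesting)", {
  spec <- ipd_sim_spec(2000, "exponential", c(rate = 0.08),
                       censor_fraction = 0.1)
  ipd <- simulate_ipd(spec, seed = 21)
  fit_w <- fit_parametric(ipd, "weibull")
  fit_e <- fit_parametric(ipd, "exponential")
  expect_equal(fit_w$curve$params$shape, 1, tolerance = 0.08)
  # one extra free parameter can only raise the maximized log-likelihood
  expect_gte(fit_w$log_likelihood, fit_e$log_likelihood - 1e-6)
})

test_that("fitting rejects degenerate inputs", {
  no_events <- data.frame(time_months = c(1, 2, 3), event = c(0, 0, 0))
  expect_error(fit_parametric(no_events, "weibull"), "2 observed events")
  one_event <- data.frame(time_months = c(1, 2, 3), event = c(1, 0, 0))
  expect_error(fit_parametric(one_event, "weibull"), "2 observed events")
  bad_time <- data.frame(time_months = c(0, 2), event = c(1, 1))
  expect_error(fit_parametric(bad_time, "weibull"), "positive")
})

test_that("exponential endpoint mode solves the landmark equation", {
  cv <- exponential_endpoint(0.5, 10)
  expect_equal(surv_median(cv), 10)
  expect_equal(survival_at(cv, 10), 0.5)
  cv2 <- exponential_endpoint(0.3, 24, "OS")
  expect_equal(survival_at(cv2, 24), 0.3)
  expect_error(exponential_endpoint(1.2, 10), "range")
})

test_that("best-fit selection minimizes AIC with documented tie-breaks", {
  fake_fit <- function(family, aic, k, n = 100) {
    params <- switch(family, exponential = c(rate = 0.1),
                     weibull = c(shape = 1, scale = 10))
    structure(list(curve = parametric_survival(family, params),
                   log_likelihood = (2 * k - aic) / 2, aic = aic,
                   bic = aic, n_events = n - 10, n_censored = 10,
                   n_params = k),
              class = "fit_result")
  }
  fits <- list(fake_fit("weibull", 102.1, 2), fake_fit("exponential", 99.4, 1),
               fake_fit("weibull", 105.0, 2))
  expect_equal(select_best_fit(fits)$aic, 99.4)

  # equal AIC: the 1-parameter fit wins
  tie <- list(fake_fit("weibull", 100, 2), fake_fit("exponential", 100, 1))
  expect_equal(select_best_fit(tie)$n_params, 1)

  # mismatched sample sizes are not comparable
  bad <- list(fake_fit("weibull", 100, 2, n = 100),
              fake_fit("exponential", 99, 1, n = 200))
  expect_error(select_best_fit(bad), "different datasets")
})

test_that("the true family is selected on large simulated samples", {
  spec <- ipd_sim_spec(4000, "weibull", c(shape = 1.8, scale = 10),
                       censor_fraction = 0.15)
  ipd <- simulate_ipd(spec, seed = 31)
  fits <- list()
  for (fam in c("exponential", "weibull", "loglogistic")) {
    fits[[fam]] <- fit_parametric(ipd, fam)
  }
  gz <- tryCatch(fit_parametric(ipd, "gompertz"), error = function(e) NULL)
  if (!is.null(gz)) fits$gompertz <- gz
  expect_identical(select_best_fit(unname(fits))$curve$family, "weibull")
})
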