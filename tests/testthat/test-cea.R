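test_that("quadrant and dominance classification match a sign-table oracle", {
  set.seed(5)
  for (i in 1:200) {
    dc <- runif(1, -2e4, 2e4)
    de <- runif(1, -0.5, 0.5)
    wtp <- runif(1, 0, 1e5)
    b <- make_result("b", cost = 5e4, qalys = 2)
    a <- make_result("a", cost = 5e4 + dc, qalys = 2 + de)
    inc <- incremental(a, b, "QALY", wtp)
    # brute-force oracle on the signs
    expect_identical(inc$quadrant,
      if (dc > 0 && de > 0) "NE" else if (dc < 0 && de > 0) "SE"
      else if (dc < 0 && de < 0) "SW" else "NW")
    expect_equal(inc$delta_cost, dc)
    expect_equal(inc$delta_effect, de)
    if (de != 0) expect_equal(inc$icer, dc / de)
    expect_identical(inc$label == "dominant", dc < 0 && de > 0)
    expect_identical(inc$label == "dominated", dc > 0 && de < 0)
  }
})

test_that("comparing an arm with itself yields no dominance and no ICER", {
  a <- make_result("a", cost = 5e4, qalys = 2)
  inc <- incremental(a, a, "QALY", 36000)
  expect_equal(inc$delta_cost, 0)
  expect_equal(inc$delta_effect, 0)
  expect_true(is.na(inc$icer))
  expect_false(inc$label %in% c("dominant", "dominated"))
})

test_that("results from different horizons refuse to be compared", {
  a <- make_result("a", cost = 1, qalys = 1, horizon = 120L)
  b <- make_result("b", cost = 2, qalys = 1, horizon = 240L)
  expect_error(incremental(a, b), "different horizons")
})

test_that("net monetary benefit is wtp * QALYs - cost", {
  r <- make_result("a", cost = 55022, qalys = 1.724)
  expect_equal(nmb(r, 0), -55022)
  expect_equal(nmb(r, 36000), 36000 * 1.724 - 55022) # 7042
  expect_error(nmb(r, -1), "range")
})

test_that("ICER threshold rule and NMB ranking agree in the NE quadrant", {
  set.seed(9)
  for (i in 1:500) {
    dc <- runif(1, 1, 5e4)
    de <- runif(1, 1e-4, 1)
    wtp <- runif(1, 0, 2e5)
    b <- make_result("b", cost = 4e4, qalys = 1.5)
    a <- make_result("a", cost = 4e4 + dc, qalys = 1.5 + de)
    inc <- incremental(a, b, "QALY", wtp)
    expect_identical(inc$label == "cost_effective",
                     nmb(a, wtp) > nmb(b, wtp))
  }
})

test_that("the deterministic pipeline reproduces its own closed-form arms", {
  cfg <- toy_config()
  res <- run_model(cfg, keep_traces = TRUE)
  expect_named(res$arm_results, c("a", "b"))
  # reference arm totals equal an accrual on independently built curves
  pfs <- parametric_survival("exponential", c(rate = 0.10), "PFS")
  os <- parametric_survival("exponential", c(rate = 0.05), "OS")
  tr <- build_trace(pfs, os, horizon = 240)
  direct <- accrue(tr, cfg$arms$a, cfg$utilities)
  expect_equal(res$arm_results$a$costs$total, direct$costs$total)
  expect_equal(res$arm_results$a$qalys$total, direct$qalys$total)
  # comparator curves carry the hazard ratios
  expect_equal(res$traces$b$pre, exp(-0.10 * 1.2 * (0:240)))
  expect_equal(1 - res$traces$b$dead, exp(-0.05 * 1.1 * (0:240)))
  # both effect measures are compared for each comparator
  expect_named(res$incrementals, c("b.QALY", "b.LY"))
})

test_that("varying a parameter with identical effect on both arms cancels", {
  cfg <- toy_config(hr_pfs_b = 1, hr_os_b = 1) # identical curves
  base <- run_model(cfg)
  sa <- one_way_sa(cfg, list(list(path = "utilities.u_pre",
                                  low = 0.55, high = 0.90)))
  # identical occupancy means utility shifts cancel in the increments
  expect_equal(sa$low_icer, base$incrementals$b.QALY$icer, tolerance = 1e-9)
  expect_equal(sa$high_icer, base$incrementals$b.QALY$icer, tolerance = 1e-9)
})

test_that("one-way sensitivity at (base, base) reproduces the base case", {
  cfg <- toy_config()
  base <- run_model(cfg)
  drug <- cfg$arms$b$pre_progression_cycle_costs$drug_acquisition
  sa <- one_way_sa(cfg, list(
    list(path = "arms.b.pre_progression_cycle_costs.drug_acquisition",
         low = drug, high = drug)))
  expect_identical(sa$low_result, sa$high_result)
  expect_equal(sa$low_icer, base$incrementals$b.QALY$icer)
})

test_that("doubling the reference arm's drug cost can flip the cost saving", {
  cfg <- toy_config(drug_b = 1300) # modest base saving for arm a
  base <- run_model(cfg)
  expect_lt(base$incrementals$b.QALY$delta_cost, 0) # a saves money
  sa <- one_way_sa(cfg, list(
    list(path = "arms.a.pre_progression_cycle_costs.drug_acquisition",
         low = 800, high = 1600)))
  expect_gt(sa$high_icer, 0) # sign flip: a now costlier but more effective
  res_high <- run_model(config_set(
    cfg, "arms.a.pre_progression_cycle_costs.drug_acquisition", 1600))
  expect_gt(res_high$incrementals$b.QALY$delta_cost, 0)
})

test_that("unresolvable parameter paths are rejected", {
  cfg <- toy_config()
  expect_error(one_way_sa(cfg, list(list(path = "arms.z.end_of_life_cost",
                                         low = 1, high = 2))),
               "does not resolve")
  expect_error(config_set(cfg, "utilities.u_mid", 0.5), "does not resolve")
  expect_equal(config_get(cfg, "arms.b.hr_pfs.links.1.hr"), 1.2)
})

test_that("survival variation through hazard multipliers moves the ICER", {
  cfg <- toy_config()
  sa <- one_way_sa(cfg, list(list(path = "survival_spec.PFS.hazard_multiplier",
                                  low = 0.5, high = 1.5)))
  res_low <- run_model(config_set(cfg, "survival_spec.PFS.hazard_multiplier",
                                  0.5))
  expect_equal(sa$low_icer, res_low$incrementals$b.QALY$icer)
  # halving the reference PFS hazard lengthens pre-progression time
  base <- run_model(cfg)
  expect_gt(res_low$arm_results$a$life_years$pre,
            base$arm_results$a$life_years$pre)
})

test_that("scenario with no overrides is the standard run", {
  cfg <- toy_config()
  expect_equal(scenario_run(cfg)$arm_results$a$costs$total,
               run_model(cfg)$arm_results$a$costs$total)
  expect_error(scenario_run(cfg, list(bogus = 1)), "unknown scenario")
})

test_that("structural scenarios change the stated machinery only", {
  cfg <- toy_config()
  base <- run_model(cfg)

  fp <- scenario_run(cfg, list(fixed_pps = 0))
  expect_lt(fp$arm_results$a$qalys$post, 1e-9)

  hc <- scenario_run(cfg, list(half_cycle_correction = TRUE))
  expect_false(isTRUE(all.equal(hc$arm_results$a$qalys$total,
                                base$arm_results$a$qalys$total)))

  rdi <- scenario_run(cfg, list(apply_rdi = TRUE))
  expect_lt(rdi$arm_results$a$costs$treatment_and_administration,
            base$arm_results$a$costs$treatment_and_administration)
})

test_that("coinciding families give identical scenario results", {
  # Weibull with shape 1 is exactly the exponential with rate 1/scale, so
  # an extrapolation-family swap between the two must leave every total
  # unchanged.
  cfg <- toy_config()
  cfg$survival_spec$PFS$alt_params <-
    list(weibull = list(shape = 1, scale = 10))
  cfg$survival_spec$OS$alt_params <-
    list(weibull = list(shape = 1, scale = 20))
  wb <- scenario_run(cfg, list(family = "weibull"))
  base <- run_model(cfg)
  expect_equal(wb$arm_results$a$costs$total, base$arm_results$a$costs$total,
               tolerance = 1e-12)
  expect_equal(wb$arm_results$b$qalys$total, base$arm_results$b$qalys$total,
               tolerance = 1e-12)
  # requesting a family with neither parameters nor data is an error
  expect_error(scenario_run(cfg, list(family = "gompertz")), "no parameters")
})
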