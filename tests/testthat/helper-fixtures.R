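# Shared fixtures: a small two-arm exponential configuration whose
# occupancy and accrual have closed forms, and a constructor for arm
# results with prescribed totals.

toy_arm <- function(id, drug = 800, reference = FALSE,
                    hr_pfs = 1, hr_os = 1) {
  arm_config(
    id,
    pre_progression_cycle_costs = list(
      drug_acquisition = drug, administration = 200, pretreatment = 50,
      lab_tests = 30, monitoring = 20),
    relative_dose_intensity = 0.9,
    post_progression_cycle_cost = 500,
    end_of_life_cost = 800,
    hr_pfs = hr_chain(hr_pfs),
    hr_os = hr_chain(hr_os),
    reference = reference
  )
}

toy_config <- function(horizon = 240, annual_discount_rate = 0.035,
                       drug_b = 1200, hr_pfs_b = 1.2, hr_os_b = 1.1,
                       scenario_flags = list()) {
  model_config(
    arms = list(toy_arm("a", reference = TRUE),
                toy_arm("b", drug = drug_b, hr_pfs = hr_pfs_b,
                        hr_os = hr_os_b)),
    utilities = utility_set(0.7733, 0.4964),
    annual_discount_rate = annual_discount_rate,
    horizon = horizon,
    wtp_threshold = 36000,
    survival_spec = list(
      PFS = list(family = "exponential", params = list(rate = 0.10)),
      OS = list(family = "exponential", params = list(rate = 0.05))
    ),
    scenario_flags = scenario_flags
  )
}

# Arm result with prescribed totals (component split arbitrary), for
# exercising the incremental stage in isolation.
make_result <- function(id, cost, qalys, ly = qalys, horizon = NA_integer_) {
  arm_result_from_components(
    id,
    costs = c(treatment_and_administration = cost, ae = 0,
              pre_progression_background = 0,
              post_progression_background = 0, terminal_care = 0),
    qalys_pre = qalys, qalys_post = 0,
    ly_pre = ly, ly_post = 0,
    horizon = horizon
  )
}

random_curve <- function(endpoint = "OS") {
  family <- sample(c("exponential", "weibull", "gompertz", "loglogistic"), 1)
  params <- switch(family,
    exponential = c(rate = runif(1, 0.01, 0.3)),
    weibull = c(shape = runif(1, 0.5, 2.5), scale = runif(1, 5, 50)),
    gompertz = c(shape = runif(1, 0.01, 0.2), rate = runif(1, 0.01, 0.1)),
    loglogistic = c(shape = runif(1, 0.8, 3), scale = runif(1, 5, 50))
  )
  parametric_survival(family, params, endpoint)
}
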