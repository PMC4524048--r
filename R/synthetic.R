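#' Specification for simulating pseudo individual-patient data
#'
#' The trial patient-level data behind the reference arm's PFS/OS are not
#' publicly deposited, so the package generates pseudo-IPD with a known
#' parametric truth: event times drawn by inverse-CDF from a declared
#' survival family, with administrative (cutoff) and/or random
#' right-censoring.
#'
#' @param n Sample size, `>= 2`.
#' @param family,params Truth distribution, as [parametric_survival()].
#' @param censor_fraction Target fraction of randomly censored subjects, in
#'   `[0, 1)`. Random censoring is non-informative: censoring times are
#'   drawn from an independent exponential distribution whose rate is
#'   solved so that the expected censored fraction equals the target
#'   (informative schemes such as uniform-on-`(0, T)` would bias the
#'   maximum-likelihood and Kaplan-Meier estimators).
#' @param admin_cutoff Administrative censoring time in months (`Inf` for
#'   none).
#' @return An object of class `ipd_sim_spec`.
#' @export
ipd_sim_spec <- function(n, family, params, censor_fraction = 0,
                         admin_cutoff = Inf) {
  stop_if_not_number(n, "n", lower = 2)
  stop_if_not_number(censor_fraction, "censor_fraction", lower = 0,
                     upper = 1, open_upper = TRUE)
  if (!(is.numeric(admin_cutoff) && length(admin_cutoff) == 1L &&
        admin_cutoff > 0)) {
    stop("admin_cutoff must be a positive time (Inf for none)",
         call. = FALSE)
  }
  truth <- parametric_survival(family, params) # validates family/params
  structure(list(n = as.integer(n), truth = truth,
                 censor_fraction = censor_fraction,
                 admin_cutoff = admin_cutoff),
            class = "ipd_sim_spec")
}

# Inverse-CDF draw: t = S^{-1}(u), u ~ U(0,1).
rsurv <- function(curve, n) {
  u <- runif(n)
  p <- curve$params
  switch(curve$family,
    exponential = -log(u) / p$rate,
    weibull     = p$scale * (-log(u))^(1 / p$shape),
    gompertz    = log(1 - p$shape * log(u) / p$rate) / p$shape,
    loglogistic = p$scale * ((1 - u) / u)^(1 / p$shape)
  )
}

# Exponential censoring rate giving the target censored fraction:
# P(C < T) = int rc * exp(-rc * c) * S_T(c) dc = target.
solve_censor_rate <- function(curve, target) {
  if (target == 0) return(0)
  p_cens <- function(rc) {
    stats::integrate(function(c) rc * exp(-rc * c) * survival_at(curve, c),
                     lower = 0, upper = Inf, rel.tol = 1e-9)$value
  }
  lo <- 1e-8
  hi <- 1
  while (p_cens(hi) < target && hi < 1e6) hi <- hi * 10
  uniroot(function(rc) p_cens(rc) - target, lower = lo, upper = hi,
          tol = 1e-10)$root
}

censor_times <- function(n, curve, censor_fraction, admin_cutoff) {
  cens <- if (censor_fraction > 0) {
    stats::rexp(n, rate = solve_censor_rate(curve, censor_fraction))
  } else {
    rep(Inf, n)
  }
  pmin(cens, admin_cutoff)
}

#' Simulate a pseudo individual-patient data table
#'
#' @param spec An [ipd_sim_spec()].
#' @param seed Integer seed; the same seed reproduces the same table and
#'   the caller's RNG state is not disturbed.
#' @return An `ipd_table` (columns `time_months`, `event`).
#' @export
#' @examples
#' spec <- ipd_sim_spec(100, "weibull", c(shape = 1.5, scale = 9),
#'                      censor_fraction = 0.2)
#' ipd <- simulate_ipd(spec, seed = 42)
simulate_ipd <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "ipd_sim_spec"))
  local_seed(seed, {
    t_event <- rsurv(spec$truth, spec$n)
    t_cens <- censor_times(spec$n, spec$truth, spec$censor_fraction,
                           spec$admin_cutoff)
    time <- pmax(pmin(t_event, t_cens), 1e-9)
    validate_ipd(data.frame(time_months = time,
                            event = as.integer(t_event <= t_cens)))
  })
}

#' Simulate consistent paired PFS and OS tables
#'
#' Per subject, a progression time is drawn from the PFS truth and a death
#' time from the OS truth; the PFS endpoint time is the componentwise
#' minimum of the two (progression cannot occur after death), so every
#' subject satisfies progression time <= death time. Each endpoint's
#' censoring scheme is then applied. A warning is emitted if the two truth
#' curves cross (PFS truth above OS truth anywhere), since downstream
#' clamping will then be active.
#'
#' @param pfs_spec,os_spec [ipd_sim_spec()]s with equal `n`.
#' @param seed Integer seed.
#' @return List with elements `pfs` and `os`, both `ipd_table`s.
#' @export
paired_ipd <- function(pfs_spec, os_spec, seed = 1L) {
  stopifnot(inherits(pfs_spec, "ipd_sim_spec"),
            inherits(os_spec, "ipd_sim_spec"))
  if (pfs_spec$n != os_spec$n) {
    stop("paired simulation requires equal sample sizes", call. = FALSE)
  }
  grid <- seq(0.5, 240, by = 0.5)
  if (any(survival_at(pfs_spec$truth, grid) >
          survival_at(os_spec$truth, grid) + 1e-9)) {
    warning("PFS truth curve lies above the OS truth curve at some times; ",
            "downstream clamping will apply", call. = FALSE)
  }
  local_seed(seed, {
    t_prog <- rsurv(pfs_spec$truth, pfs_spec$n)
    t_death <- rsurv(os_spec$truth, os_spec$n)
    t_pfs <- pmin(t_prog, t_death)
    c_pfs <- censor_times(pfs_spec$n, pfs_spec$truth,
                          pfs_spec$censor_fraction, pfs_spec$admin_cutoff)
    c_os <- censor_times(os_spec$n, os_spec$truth,
                         os_spec$censor_fraction, os_spec$admin_cutoff)
    list(
      pfs = validate_ipd(data.frame(
        time_months = pmax(pmin(t_pfs, c_pfs), 1e-9),
        event = as.integer(t_pfs <= c_pfs))),
      os = validate_ipd(data.frame(
        time_months = pmax(pmin(t_death, c_os), 1e-9),
        event = as.integer(t_death <= c_os)))
    )
  })
}

#' Packaged base-case configuration fixture
#'
#' A complete three-arm configuration for second-line HR+/HER2- metastatic
#' breast cancer: everolimus + exemestane (`eve_exe`, the reference arm)
#' versus bevacizumab + paclitaxel (`bev_pacl`) and bevacizumab +
#' capecitabine (`bev_cape`). All cost inputs carry the published per-cycle
#' values (2013/2014 Greek prices): e.g. drug acquisition 2,447.75 /
#' 3,806.42 / 3,510.97 euros per cycle, an aggregate post-progression cost
#' of 1,057.41 euros/cycle and an end-of-life cost of 823.60 euros;
#' utilities 0.7733 (pre) / 0.4964 (post); 3.5\% annual discounting; WTP
#' 36,000 euros/QALY. Adverse-event profiles are synthetic rows calibrated
#' so the expected one-off cost and disutility per arm equal the published
#' aggregates (62 / 5.14 / 1 euros; -0.029 / -0.027 / -0.0031 QALYs).
#'
#' The survival parameters (Weibull PFS/OS for the reference arm) and the
#' comparator hazard-ratio chains are SYNTHETIC placeholders: the source
#' analysis prints neither its fitted Weibull parameters nor its numeric
#' indirect-comparison HRs. The placeholders are loosely evocative of
#' advanced-breast-cancer trajectories (PFS median about 7.5 months, OS
#' median about 26 months) and must not be read as estimates of any trial.
#'
#' @return A validated [model_config].
#' @export
base_case_fixture <- function() {
  eve_exe <- arm_config(
    "eve_exe",
    pre_progression_cycle_costs = list(
      drug_acquisition = 2447.75, administration = 0, pretreatment = 0,
      lab_tests = 42.82, monitoring = 52.34, prophylaxis = 0),
    relative_dose_intensity = 0.87, # blended EVE 86% / EXE 100%, synthetic
    ae_profile = data.frame(
      event = c("pneumonitis", "anemia", "nausea"),
      frequency = c(0.03, 0.06, 0.08),
      unit_cost = c(1200, 300, 100),
      disutility = c(-0.40, -0.15, -0.10)),
    reference = TRUE)
  bev_pacl <- arm_config(
    "bev_pacl",
    pre_progression_cycle_costs = list(
      drug_acquisition = 3806.42, administration = 260.89,
      pretreatment = 82.58, lab_tests = 52.41, monitoring = 52.34,
      prophylaxis = 274.72),
    relative_dose_intensity = 0.86,
    ae_profile = data.frame(
      event = c("neutropenia", "nausea", "arthralgia"),
      frequency = c(0.02, 0.01, 0.10),
      unit_cost = c(207, 100, 0),
      disutility = c(-0.40, -0.40, -0.15)),
    hr_pfs = hr_chain(1.30, "indirect chain (synthetic)"),
    hr_os = hr_chain(0.98, "indirect chain (synthetic)"))
  bev_cape <- arm_config(
    "bev_cape",
    pre_progression_cycle_costs = list(
      drug_acquisition = 3510.97, administration = 115.95,
      pretreatment = 36.69, lab_tests = 48.25, monitoring = 52.34,
      prophylaxis = 416.77),
    relative_dose_intensity = 0.86,
    ae_profile = data.frame(
      event = c("vomiting", "myalgia"),
      frequency = c(0.005, 0.01),
      unit_cost = c(200, 0),
      disutility = c(-0.22, -0.20)),
    hr_pfs = hr_chain(1.49, "indirect chain (synthetic)"),
    hr_os = hr_chain(0.96, "indirect chain (synthetic)"))

  model_config(
    arms = list(eve_exe, bev_pacl, bev_cape),
    utilities = utility_set(0.7733, 0.4964),
    annual_discount_rate = 0.035,
    horizon = 180,
    wtp_threshold = 36000,
    survival_spec = list(
      PFS = list(family = "weibull",
                 params = list(shape = 1.3, scale = 10)), # synthetic
      OS = list(family = "weibull",
                params = list(shape = 1.3, scale = 34))   # synthetic
    )
  )
}
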