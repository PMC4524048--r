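DEFAULT_SCENARIO_FLAGS <- list(
  half_cycle_correction = FALSE,
  discount_from_start = FALSE,
  apply_rdi = FALSE,
  fixed_post_progression_survival_months = NULL
)

#' Assemble a full model configuration
#'
#' The configuration is the single source of every model input: the arms
#' and their economic profiles, health-state utilities, discounting, time
#' horizon, willingness-to-pay threshold, the reference arm's survival
#' specification and the structural scenario flags. All invariants are
#' checked on construction; any violating configuration is rejected before
#' computation starts.
#'
#' @param arms List of [arm_config]s; exactly one must be flagged
#'   `reference`.
#' @param utilities A [utility_set].
#' @param annual_discount_rate Annual discount rate in `[0, 1)`.
#' @param cycle_length Cycle length in months; the cohort trace is monthly,
#'   so only 1 is supported.
#' @param horizon Model horizon in months, at least one cycle.
#' @param wtp_threshold Willingness to pay in euros per QALY, > 0.
#' @param survival_spec List with elements `PFS` and `OS`; each endpoint is
#'   either declared (`family` + `params`) or fitted (`ipd`, an IPD table,
#'   with `family` naming a family or `"best"` for minimum-AIC selection
#'   across all four). Optional per-endpoint fields: `hazard_multiplier`
#'   (> 0, default 1; a proportional-hazards scaling used by sensitivity
#'   analyses) and `alt_params` (named list of per-family parameter sets
#'   for extrapolation-method scenarios).
#' @param scenario_flags List of structural switches:
#'   `half_cycle_correction`, `discount_from_start`, `apply_rdi` (logicals)
#'   and `fixed_post_progression_survival_months` (number or `NULL`).
#' @return A validated object of class `model_config`.
#' @export
model_config <- function(arms,
                         utilities = utility_set(),
                         annual_discount_rate = 0.035,
                         cycle_length = 1,
                         horizon = 180,
                         wtp_threshold = 36000,
                         survival_spec,
                         scenario_flags = list()) {
  if (length(arms) < 1L) stop("at least one arm is required", call. = FALSE)
  ids <- vapply(arms, function(a) a$arm_id, character(1))
  names(arms) <- ids
  flags <- utils::modifyList(DEFAULT_SCENARIO_FLAGS, scenario_flags,
                             keep.null = TRUE)
  cfg <- structure(
    list(arms = arms,
         reference_arm_id = ids[vapply(arms, function(a) a$reference,
                                       logical(1))][1],
         utilities = utilities,
         annual_discount_rate = annual_discount_rate,
         cycle_length = cycle_length,
         horizon = horizon,
         wtp_threshold = wtp_threshold,
         survival_spec = survival_spec,
         scenario_flags = flags),
    class = "model_config"
  )
  validate_model_config(cfg)
}

#' Validate a model configuration
#'
#' Checks every typed invariant (discount rate, horizon, reference-arm
#' uniqueness, utility ordering, cost signs, adverse-event frequencies,
#' hazard-ratio positivity, survival-specification completeness) and
#' refreshes derived fields (chain combined HRs). Called by [model_config()]
#' and again by [run_model()], so a configuration mutated by a sensitivity
#' analysis is re-checked before use.
#'
#' @param config A `model_config`.
#' @return The validated configuration (invisibly usable), with derived
#'   fields refreshed.
#' @export
validate_model_config <- function(config) {
  if (!inherits(config, "model_config")) {
    stop("not a model_config", call. = FALSE)
  }
  stop_if_not_number(config$annual_discount_rate, "annual_discount_rate",
                     lower = 0, upper = 1, open_upper = TRUE)
  if (!identical(as.numeric(config$cycle_length), 1)) {
    stop("only a monthly cycle (cycle_length = 1) is supported",
         call. = FALSE)
  }
  stop_if_not_number(config$horizon, "horizon", lower = 1)
  stop_if_not_number(config$wtp_threshold, "wtp_threshold",
                     lower = 0, open_lower = TRUE)

  n_ref <- sum(vapply(config$arms, function(a) isTRUE(a$reference),
                      logical(1)))
  if (n_ref != 1L) {
    stop("exactly one arm must be flagged as reference (found ", n_ref, ")",
         call. = FALSE)
  }
  ref_id <- names(config$arms)[vapply(config$arms,
                                      function(a) a$reference, logical(1))]
  if (!identical(config$reference_arm_id, ref_id)) {
    stop("reference_arm_id ('", config$reference_arm_id,
         "') disagrees with the arm flagged reference ('", ref_id, "')",
         call. = FALSE)
  }
  if (anyDuplicated(names(config$arms))) {
    stop("duplicated arm_id in configuration", call. = FALSE)
  }

  u <- config$utilities
  config$utilities <- utility_set(u$u_pre, u$u_post) # re-checks ordering

  config$arms <- lapply(config$arms, function(a) {
    # rebuild through the constructor so post-mutation states are re-checked
    arm_config(a$arm_id, a$pre_progression_cycle_costs,
               a$relative_dose_intensity, a$post_progression_cycle_cost,
               a$end_of_life_cost, a$ae_profile,
               refresh_chain(a$hr_pfs), refresh_chain(a$hr_os),
               a$reference)
  })

  for (ep in c("PFS", "OS")) {
    sp <- config$survival_spec[[ep]]
    if (is.null(sp)) {
      stop("survival_spec lacks the required endpoint '", ep, "'",
           call. = FALSE)
    }
    if (is.null(sp[["params"]]) && is.null(sp[["ipd"]]) &&
        is.null(sp[["ipd_path"]])) {
      stop("survival_spec$", ep,
           " needs either declared 'params' or 'ipd'/'ipd_path' to fit",
           call. = FALSE)
    }
    if (!is.null(sp[["params"]])) {
      parametric_survival(sp[["family"]], sp[["params"]], ep) # construction validates
    } else {
      if (is.null(sp[["family"]])) {
        stop("survival_spec$", ep, " with ipd needs a 'family' ",
             "(or \"best\")", call. = FALSE)
      }
      if (!is.null(sp[["ipd"]])) validate_ipd(sp[["ipd"]])
    }
    hm <- sp$hazard_multiplier
    if (!is.null(hm)) {
      stop_if_not_number(hm, paste0("survival_spec$", ep,
                                    "$hazard_multiplier"),
                         lower = 0, open_lower = TRUE)
    } else {
      config$survival_spec[[ep]]$hazard_multiplier <- 1
    }
  }

  flags <- config$scenario_flags
  for (f in c("half_cycle_correction", "discount_from_start", "apply_rdi")) {
    if (!is.logical(flags[[f]]) || length(flags[[f]]) != 1L ||
        is.na(flags[[f]])) {
      stop("scenario flag '", f, "' must be TRUE or FALSE", call. = FALSE)
    }
  }
  fpps <- flags$fixed_post_progression_survival_months
  if (!is.null(fpps)) {
    stop_if_not_number(fpps, "fixed_post_progression_survival_months",
                       lower = 0)
  }
  config
}

refresh_chain <- function(chain) {
  if (!inherits(chain, "hr_chain")) {
    stop("hazard-ratio chain field does not hold an hr_chain", call. = FALSE)
  }
  hr_chain(vapply(chain$links, function(l) l$hr, numeric(1)),
           vapply(chain$links, function(l) as.character(l$label),
                  character(1)))
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config> %d arms (reference: %s), horizon %d months\n",
              length(x$arms), x$reference_arm_id, as.integer(x$horizon)))
  cat(sprintf("  discount %.1f%%/yr | WTP %s EUR/QALY | u_pre %.4f u_post %.4f\n",
              100 * x$annual_discount_rate,
              format(x$wtp_threshold, big.mark = ","),
              x$utilities$u_pre, x$utilities$u_post))
  invisible(x)
}
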