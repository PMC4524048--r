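reference_curve <- function(config, endpoint) {
  sp <- config$survival_spec[[endpoint]]
  if (is.null(sp[["ipd"]]) && !is.null(sp[["ipd_path"]])) {
    sp[["ipd"]] <- read_ipd(sp[["ipd_path"]])
  }
  curve <- if (!is.null(sp[["params"]])) {
    parametric_survival(sp[["family"]], sp[["params"]], endpoint)
  } else if (identical(sp[["family"]], "best")) {
    fits <- list()
    for (fam in SURV_FAMILIES) {
      f <- tryCatch(fit_parametric(sp[["ipd"]], fam, endpoint),
                    error = function(e) NULL)
      if (!is.null(f)) fits[[fam]] <- f
    }
    if (!length(fits)) {
      stop("no parametric family could be fitted to the ", endpoint, " IPD",
           call. = FALSE)
    }
    select_best_fit(unname(fits))$curve
  } else {
    fit_parametric(sp[["ipd"]], sp[["family"]], endpoint)$curve
  }
  hm <- sp$hazard_multiplier %||% 1
  if (hm != 1) curve <- apply_hazard_ratio(curve, hm)
  curve
}

#' Run the full deterministic cost-effectiveness pipeline
#'
#' For the reference arm the PFS and OS curves come from the survival
#' specification (declared parameters or a fit to pseudo-IPD); for every
#' comparator they are obtained by applying the arm's hazard-ratio chains
#' to the reference curves. PFS is then clamped at or below OS, the monthly
#' partitioned-survival trace is built over the horizon, costs and
#' (quality-adjusted) life years are accrued per arm, and the reference arm
#' is compared incrementally against each comparator on both the QALY and
#' the life-year scale.
#'
#' @param config A [model_config].
#' @param validate Revalidate the configuration first (default; switch off
#'   only on hot loops that already validated).
#' @param keep_traces Attach the per-arm cohort traces to the result.
#' @return An object of class `cea_results`: `arm_results` (named list of
#'   [accrue()] results), `incrementals` (one [incremental()] result per
#'   comparator and effect measure), `wtp_threshold`, `reference_arm_id`
#'   and optionally `traces`.
#' @export
run_model <- function(config, validate = TRUE, keep_traces = FALSE) {
  if (validate) config <- validate_model_config(config)
  flags <- config$scenario_flags
  pfs0 <- reference_curve(config, "PFS")
  os0 <- reference_curve(config, "OS")

  arm_results <- list()
  traces <- list()
  for (arm in config$arms) {
    if (arm$reference) {
      pfs <- pfs0
      os <- os0
    } else {
      pfs <- apply_hazard_ratio(pfs0, arm$hr_pfs)
      os <- apply_hazard_ratio(os0, arm$hr_os)
    }
    trace <- build_trace(clamp_pfs(pfs, os), os,
                         horizon = config$horizon,
                         fixed_pps = flags$fixed_post_progression_survival_months,
                         annual_rate = config$annual_discount_rate,
                         from_start = flags$discount_from_start)
    arm_results[[arm$arm_id]] <- accrue(
      trace, arm, config$utilities,
      disutility_on = TRUE,
      apply_rdi = flags$apply_rdi,
      half_cycle = flags$half_cycle_correction)
    if (keep_traces) traces[[arm$arm_id]] <- trace
  }

  ref <- arm_results[[config$reference_arm_id]]
  incrementals <- list()
  for (id in setdiff(names(arm_results), config$reference_arm_id)) {
    for (measure in c("QALY", "LY")) {
      incrementals[[paste0(id, ".", measure)]] <-
        incremental(ref, arm_results[[id]], measure = measure,
                    wtp = config$wtp_threshold)
    }
  }
  out <- list(arm_results = arm_results, incrementals = incrementals,
              wtp_threshold = config$wtp_threshold,
              reference_arm_id = config$reference_arm_id)
  if (keep_traces) out$traces <- traces
  structure(out, class = "cea_results")
}

#' Incremental cost-effectiveness comparison of two arms
#'
#' Computes `delta_cost = cost(a) - cost(b)` and
#' `delta_effect = effect(a) - effect(b)` (discounted QALYs or discounted
#' life years), classifies the cost-effectiveness-plane quadrant, and
#' labels the result: southeast (cheaper, more effective) is `dominant`;
#' northwest (costlier, less effective) is `dominated`; northeast reports
#' the ICER and is `cost_effective` when `ICER <= wtp`; southwest — cheaper
#' but less effective — is labelled `less_effective_and_cheaper` with the
#' ICER still reported (interpretable as savings per unit of effect
#' forgone). If `delta_effect` is exactly zero the ICER is undefined and
#' the label falls back to the sign of the incremental net monetary
#' benefit.
#'
#' @param a,b [accrue()] results (`a` is the intervention of interest).
#' @param measure Effect measure, `"QALY"` or `"LY"` (discounted).
#' @param wtp Willingness-to-pay threshold in euros per effect unit.
#' @return An object of class `incremental_result` with fields
#'   `comparator_pair`, `delta_cost`, `delta_effect`, `effect_measure`,
#'   `icer` (`NA` when undefined), `label`, `quadrant`.
#' @export
incremental <- function(a, b, measure = c("QALY", "LY"), wtp = 36000) {
  measure <- match.arg(measure)
  stopifnot(inherits(a, "arm_result"), inherits(b, "arm_result"))
  if (!is.na(a$horizon) && !is.na(b$horizon) &&
      !identical(a$horizon, b$horizon)) {
    stop("arm results come from different horizons (", a$horizon, " vs ",
         b$horizon, " months)", call. = FALSE)
  }
  eff <- function(x) switch(measure, QALY = x$qalys$total,
                            LY = x$life_years$total)
  dc <- a$costs$total - b$costs$total
  de <- eff(a) - eff(b)
  icer <- if (de != 0) dc / de else NA_real_
  quadrant <- if (dc == 0 || de == 0) NA_character_
    else if (dc > 0 && de > 0) "NE"
    else if (dc < 0 && de > 0) "SE"
    else if (dc < 0 && de < 0) "SW"
    else "NW"
  label <-
    if (de > 0 && dc < 0) "dominant"
    else if (de < 0 && dc > 0) "dominated"
    else if (de < 0 && dc < 0) "less_effective_and_cheaper"
    else if (de > 0 && dc > 0) {
      if (icer <= wtp) "cost_effective" else "not_cost_effective"
    } else {
      # boundary: delta_effect == 0 and/or delta_cost == 0
      if (wtp * de - dc >= 0) "cost_effective" else "not_cost_effective"
    }
  structure(
    list(comparator_pair = c(a$arm_id, b$arm_id),
         delta_cost = dc, delta_effect = de, effect_measure = measure,
         icer = icer, label = label, quadrant = quadrant, wtp = wtp),
    class = "incremental_result"
  )
}

#' @export
print.incremental_result <- function(x, ...) {
  cat(sprintf("<incremental> %s vs %s (%s)\n", x$comparator_pair[1],
              x$comparator_pair[2], x$effect_measure))
  cat(sprintf("  delta cost %+.0f EUR | delta effect %+.3f | %s",
              x$delta_cost, x$delta_effect, x$label))
  if (!is.na(x$icer)) cat(sprintf(" | ICER %.0f EUR/%s", x$icer,
                                  x$effect_measure))
  cat("\n")
  invisible(x)
}

#' Net monetary benefit
#'
#' `NMB = wtp * total QALYs - total cost`; between two arms, a higher NMB
#' at a given willingness to pay is equivalent to the ICER decision rule.
#'
#' @param result An [accrue()] result, or a list with `qalys$total` and
#'   `costs$total`.
#' @param wtp Willingness to pay in euros per QALY, `>= 0`.
#' @return Euros.
#' @export
nmb <- function(result, wtp) {
  stop_if_not_number(wtp, "willingness to pay", lower = 0)
  wtp * result$qalys$total - result$costs$total
}

#' One-way (deterministic) sensitivity analysis
#'
#' Reruns the full deterministic pipeline with one parameter at a time set
#' to its low and high value (everything else at base case) and reports,
#' per comparator, the resulting QALY-based ICER or dominance label.
#' Parameters are addressed by dotted configuration paths (see
#' [config_set()]); survival variations are expressed through hazard-ratio
#' link paths (comparator arms) or the reference curves'
#' `survival_spec.<endpoint>.hazard_multiplier`.
#'
#' @param config A [model_config].
#' @param param_specs List of `list(path, low, high)` (or a data frame with
#'   those columns); `low <= high`.
#' @return Data frame with one row per parameter and comparator: columns
#'   `parameter`, `comparator`, `base_value`, `low_value`, `high_value`,
#'   `low_icer`, `high_icer` (`NA` where undefined), `low_result`,
#'   `high_result` (ICER formatted in euros, or the dominance label).
#' @export
one_way_sa <- function(config, param_specs) {
  config <- validate_model_config(config)
  if (is.data.frame(param_specs)) {
    param_specs <- lapply(seq_len(nrow(param_specs)), function(i)
      as.list(param_specs[i, ]))
  }
  comparators <- setdiff(names(config$arms), config$reference_arm_id)
  rows <- list()
  for (spec in param_specs) {
    if (is.null(spec$path)) stop("each parameter spec needs a 'path'",
                                 call. = FALSE)
    if (spec$low > spec$high) {
      stop("low > high for parameter '", spec$path, "'", call. = FALSE)
    }
    base_value <- config_get(config, spec$path)
    run_at <- function(value) {
      run_model(config_set(config, spec$path, value), validate = TRUE)
    }
    res_low <- run_at(spec$low)
    res_high <- run_at(spec$high)
    for (cmp in comparators) {
      inc_l <- res_low$incrementals[[paste0(cmp, ".QALY")]]
      inc_h <- res_high$incrementals[[paste0(cmp, ".QALY")]]
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = spec$path, comparator = cmp,
        base_value = as.numeric(base_value),
        low_value = spec$low, high_value = spec$high,
        low_icer = inc_l$icer, high_icer = inc_h$icer,
        low_result = owsa_cell(inc_l), high_result = owsa_cell(inc_h),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

owsa_cell <- function(inc) {
  if (inc$label %in% c("dominant", "dominated", "less_effective_and_cheaper")) {
    inc$label
  } else {
    sprintf("%.0f EUR/%s", inc$icer, inc$effect_measure)
  }
}

#' Run a structural scenario
#'
#' Reruns the deterministic pipeline under a stated structural variant:
#' an alternative extrapolation family, an alternative survival input set
#' (e.g. a different radiological assessment of PFS), fixed
#' post-progression survival, half-cycle correction, dose-intensity
#' adjustment, or the from-start discounting convention.
#'
#' @param config A [model_config].
#' @param overrides Named list; recognised names: `family` (refits or
#'   swaps in per-family `alt_params` for both endpoints),
#'   `survival_spec` (full replacement), `fixed_pps` (months),
#'   `half_cycle_correction`, `apply_rdi`, `discount_from_start`
#'   (logicals).
#' @return A `cea_results` object, as [run_model()].
#' @export
scenario_run <- function(config, overrides = list()) {
  config <- validate_model_config(config)
  known <- c("family", "survival_spec", "fixed_pps",
             "half_cycle_correction", "apply_rdi", "discount_from_start")
  unknown <- setdiff(names(overrides), known)
  if (length(unknown)) {
    stop("unknown scenario override(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(overrides$survival_spec)) {
    config$survival_spec <- overrides$survival_spec
  }
  if (!is.null(overrides$family)) {
    fam <- match.arg(overrides$family, SURV_FAMILIES)
    for (ep in c("PFS", "OS")) {
      sp <- config$survival_spec[[ep]]
      if (!is.null(sp[["alt_params"]][[fam]])) {
        sp[["params"]] <- sp[["alt_params"]][[fam]]
        sp[["family"]] <- fam
      } else if (!is.null(sp[["ipd"]])) {
        sp[["family"]] <- fam
        sp[["params"]] <- NULL
      } else if (!identical(sp[["family"]], fam)) {
        stop("no parameters or IPD available to use the '", fam,
             "' family for ", ep, call. = FALSE)
      }
      config$survival_spec[[ep]] <- sp
    }
  }
  if (!is.null(overrides$fixed_pps)) {
    config$scenario_flags$fixed_post_progression_survival_months <-
      overrides$fixed_pps
  }
  for (f in c("half_cycle_correction", "apply_rdi", "discount_from_start")) {
    if (!is.null(overrides[[f]])) config$scenario_flags[[f]] <- overrides[[f]]
  }
  run_model(config)
}

#' @export
print.cea_results <- function(x, ...) {
  cat(sprintf("<cea_results> reference arm: %s | WTP %s EUR/QALY\n",
              x$reference_arm_id, format(x$wtp_threshold, big.mark = ",")))
  for (ar in x$arm_results) {
    cat(sprintf("  %-10s total cost %10s EUR | QALYs %6.3f | LYs %6.3f\n",
                ar$arm_id,
                format(round_half_up(ar$costs$total), big.mark = ","),
                ar$qalys$total, ar$life_years$total))
  }
  for (inc in x$incrementals) {
    cat(sprintf("  %s vs %s (%s): delta cost %+.0f, delta effect %+.3f -> %s\n",
                inc$comparator_pair[1], inc$comparator_pair[2],
                inc$effect_measure, inc$delta_cost, inc$delta_effect,
                owsa_cell(inc)))
  }
  invisible(x)
}
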