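PRE_COST_COMPONENTS <- c("drug_acquisition", "administration", "pretreatment",
                         "lab_tests", "monitoring", "prophylaxis")

#' Per-arm economic inputs
#'
#' Bundles everything the model needs to cost one treatment arm: the
#' pre-progression per-cycle cost components, relative dose intensity (RDI),
#' the aggregate post-progression per-cycle cost, the one-off end-of-life
#' (terminal care) cost, the grade 3/4 adverse-event profile, and the
#' hazard-ratio chains linking the arm's PFS/OS to the reference arm.
#'
#' @param arm_id Identifier, unique within a configuration.
#' @param pre_progression_cycle_costs Named list in euros/cycle; recognised
#'   components are `drug_acquisition`, `administration`, `pretreatment`,
#'   `lab_tests`, `monitoring`, `prophylaxis`; omitted components default
#'   to 0.
#' @param relative_dose_intensity Fraction of planned dose received, in
#'   (0, 1]; scales the drug-acquisition cost when the RDI scenario flag is
#'   on.
#' @param post_progression_cycle_cost Euros per cycle in the
#'   post-progression state.
#' @param end_of_life_cost One-off euros attached to the cycle of death.
#' @param ae_profile Data frame with columns `event`, `frequency` (in
#'   `[0,1]`), `unit_cost` (euros, `>= 0`), `disutility` (QALY decrement,
#'   `<= 0`); `NULL` for an empty profile.
#' @param hr_pfs,hr_os [hr_chain]s versus the reference arm (identity for
#'   the reference arm itself).
#' @param reference Logical; is this the reference arm?
#' @return An object of class `arm_config`.
#' @export
arm_config <- function(arm_id,
                       pre_progression_cycle_costs,
                       relative_dose_intensity = 1,
                       post_progression_cycle_cost = 1057.41,
                       end_of_life_cost = 823.60,
                       ae_profile = NULL,
                       hr_pfs = hr_chain(1, "reference"),
                       hr_os = hr_chain(1, "reference"),
                       reference = FALSE) {
  stopifnot(is.character(arm_id), length(arm_id) == 1L, nzchar(arm_id))
  costs <- as.list(pre_progression_cycle_costs)
  unknown <- setdiff(names(costs), PRE_COST_COMPONENTS)
  if (length(unknown)) {
    stop("unknown pre-progression cost component(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  full <- setNames(as.list(rep(0, length(PRE_COST_COMPONENTS))),
                   PRE_COST_COMPONENTS)
  full[names(costs)] <- costs
  for (nm in PRE_COST_COMPONENTS) {
    stop_if_not_number(full[[nm]], paste0(arm_id, " ", nm), lower = 0)
  }
  stop_if_not_number(relative_dose_intensity,
                     paste0(arm_id, " relative_dose_intensity"),
                     lower = 0, upper = 1, open_lower = TRUE)
  stop_if_not_number(post_progression_cycle_cost,
                     paste0(arm_id, " post_progression_cycle_cost"), lower = 0)
  stop_if_not_number(end_of_life_cost,
                     paste0(arm_id, " end_of_life_cost"), lower = 0)
  ae_profile <- validate_ae_profile(ae_profile, arm_id)
  if (!inherits(hr_pfs, "hr_chain") || !inherits(hr_os, "hr_chain")) {
    stop("hr_pfs and hr_os must be hr_chain objects", call. = FALSE)
  }
  structure(
    list(arm_id = arm_id,
         pre_progression_cycle_costs = full,
         relative_dose_intensity = relative_dose_intensity,
         post_progression_cycle_cost = post_progression_cycle_cost,
         end_of_life_cost = end_of_life_cost,
         ae_profile = ae_profile,
         hr_pfs = hr_pfs, hr_os = hr_os,
         reference = isTRUE(reference)),
    class = "arm_config"
  )
}

validate_ae_profile <- function(ae_profile, arm_id = "arm") {
  if (is.null(ae_profile) || (is.data.frame(ae_profile) && nrow(ae_profile) == 0L)) {
    return(data.frame(event = character(), frequency = numeric(),
                      unit_cost = numeric(), disutility = numeric()))
  }
  ae_profile <- as.data.frame(ae_profile)
  need <- c("event", "frequency", "unit_cost", "disutility")
  missing <- setdiff(need, names(ae_profile))
  if (length(missing)) {
    stop(arm_id, " ae_profile lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(ae_profile$frequency < 0 | ae_profile$frequency > 1)) {
    stop(arm_id, " adverse-event frequencies must lie in [0, 1]",
         call. = FALSE)
  }
  if (any(ae_profile$unit_cost < 0)) {
    stop(arm_id, " adverse-event unit costs must be >= 0", call. = FALSE)
  }
  if (any(ae_profile$disutility > 0)) {
    stop(arm_id, " adverse-event disutilities are QALY decrements and must ",
         "be <= 0", call. = FALSE)
  }
  ae_profile[, need]
}

#' Health-state utility weights
#'
#' Annual utility weights for the two alive states; the per-cycle QALY
#' contribution of a state is `occupancy * u * cycle_length / 12`.
#'
#' @param u_pre Pre-progression utility, in `[0, 1]`.
#' @param u_post Post-progression utility, `0 <= u_post <= u_pre`.
#' @return An object of class `utility_set`.
#' @export
utility_set <- function(u_pre = 0.7733, u_post = 0.4964) {
  stop_if_not_number(u_pre, "u_pre", lower = 0, upper = 1)
  stop_if_not_number(u_post, "u_post", lower = 0, upper = 1)
  if (u_post > u_pre) {
    stop("post-progression utility (", u_post,
         ") exceeds pre-progression utility (", u_pre, ")", call. = FALSE)
  }
  structure(list(u_pre = u_pre, u_post = u_post), class = "utility_set")
}

#' Reimbursed drug price under the Greek distribution channels
#'
#' The price the payer reimburses depends on how the drug reaches the
#' patient: hospital-administered drugs carry a 5\% mark-up on the hospital
#' price, high-cost drugs dispensed through outpatient pharmacies a 5\%
#' rebate, and retail-dispensed drugs are reimbursed at the supplied
#' social-security price unchanged.
#'
#' @param price Hospital or retail price in euros, > 0.
#' @param channel One of `"hospital_markup"`, `"outpatient_rebate"`,
#'   `"retail"`.
#' @return Reimbursed price in euros.
#' @export
#' @examples
#' reimbursed_price(100, "hospital_markup")  # 105
#' reimbursed_price(100, "outpatient_rebate") # 95
reimbursed_price <- function(price,
                             channel = c("hospital_markup",
                                         "outpatient_rebate", "retail")) {
  stop_if_not_number(price, "price", lower = 0, open_lower = TRUE)
  channel <- match.arg(channel)
  switch(channel,
    hospital_markup = price * 1.05,
    outpatient_rebate = price * 0.95,
    retail = price
  )
}

#' Total pre-progression cost per cycle for an arm
#'
#' Sum of the six per-cycle components; relative dose intensity, when
#' applied, scales the drug-acquisition component only (a reduced dose
#' reduces drug consumed, not infusion visits or monitoring).
#'
#' @param arm An [arm_config].
#' @param apply_rdi Logical; scale drug acquisition by the arm's RDI.
#' @return Euros per cycle.
#' @export
cycle_cost_pre <- function(arm, apply_rdi = FALSE) {
  cc <- arm$pre_progression_cycle_costs
  drug <- cc$drug_acquisition * if (apply_rdi) arm$relative_dose_intensity else 1
  drug + cc$administration + cc$pretreatment + cc$lab_tests +
    cc$monitoring + cc$prophylaxis
}

#' One-off adverse-event cost and QALY decrement
#'
#' Grade 3/4 adverse-event management is costed as a one-off applied at
#' model entry (cycle 0, undiscounted): expected cost
#' `sum(frequency * unit_cost)` and expected QALY decrement
#' `sum(frequency * disutility)` (a non-positive number).
#'
#' @param arm An [arm_config].
#' @return List with elements `cost` (euros) and `qaly_decrement` (QALYs,
#'   `<= 0`).
#' @export
ae_one_off <- function(arm) {
  p <- arm$ae_profile
  list(cost = sum(p$frequency * p$unit_cost),
       qaly_decrement = sum(p$frequency * p$disutility))
}

#' Average monthly cost in the post-progression state
#'
#' Patients progressing are allocated across mutually exclusive
#' post-progression treatment strategies (e.g. 50/50 between a
#' hormonal-then-chemo sequence and a chemo-only sequence). Within each
#' strategy, the monthly cost of each treatment line is weighted by the
#' line's duration; the strategy means are then weight-averaged across
#' strategies.
#'
#' @param strategies List of strategies, each a list with elements `weight`
#'   (allocation fraction; weights must sum to 1) and `lines`, a list of
#'   treatment lines each holding `monthly_cost` (euros, `>= 0`) and
#'   `duration` (months, `> 0`); a `label` per line is optional.
#' @return Euros per month.
#' @export
#' @examples
#' post_progression_cycle_cost(list(
#'   list(weight = 0.5, lines = list(
#'     list(monthly_cost = 1200, duration = 12),
#'     list(monthly_cost = 600, duration = 6))),
#'   list(weight = 0.5, lines = list(
#'     list(monthly_cost = 900, duration = 12),
#'     list(monthly_cost = 1500, duration = 6)))
#' )) # 1050
post_progression_cycle_cost <- function(strategies) {
  if (length(strategies) < 1L) stop("no strategies supplied", call. = FALSE)
  w <- vapply(strategies, function(s) s$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-9) {
    stop("strategy weights sum to ", sum(w), ", not 1", call. = FALSE)
  }
  means <- vapply(strategies, function(s) {
    if (length(s$lines) < 1L) stop("a strategy has no treatment lines",
                                   call. = FALSE)
    cost <- vapply(s$lines, function(l) l$monthly_cost, numeric(1))
    dur <- vapply(s$lines, function(l) l$duration, numeric(1))
    if (any(dur <= 0) || any(cost < 0)) {
      stop("treatment lines need duration > 0 and monthly_cost >= 0",
           call. = FALSE)
    }
    sum(cost * dur) / sum(dur)
  }, numeric(1))
  sum(w * means)
}

#' Accrue costs, QALYs and life-years over a cohort trace
#'
#' Walks the trace cycle by cycle and accumulates the five cost components
#' (treatment and administration, adverse events, pre-progression
#' background, post-progression background, terminal care) and the
#' quality-adjusted and unadjusted survival, discounted and undiscounted.
#' Per cycle `t` (covering `(t-1, t]`):
#' \itemize{
#'   \item treatment & administration: `pre(t) * (drug [* RDI] + admin) * df`
#'   \item pre-progression background: `pre(t) * (pretreatment + labs +
#'     monitoring + prophylaxis) * df`
#'   \item post-progression background: `post(t) * post_cycle_cost * df`
#'   \item terminal care: `new_deaths(t) * end_of_life_cost * df`
#'   \item QALYs: `(pre(t) * u_pre + post(t) * u_post) / 12 * df`; life
#'     years identically with utility 1.
#' }
#' The adverse-event cost and QALY decrement are added once at entry,
#' undiscounted; the decrement is booked against the pre-progression QALY
#' component (events occur on treatment). With `half_cycle = TRUE` the
#' occupancy of each cycle is the average of its start and end values.
#'
#' @param trace A [build_trace()] result.
#' @param arm An [arm_config].
#' @param utilities A [utility_set].
#' @param disutility_on Logical; include adverse-event disutilities.
#' @param apply_rdi Logical; scale drug acquisition by RDI.
#' @param half_cycle Logical; half-cycle-correct state occupancy.
#' @return An object of class `arm_result`: `costs` (the five discounted
#'   components and `total`), `qalys` (`pre`, `post`, `total`),
#'   `life_years` (`pre`, `post`, `total`) and `life_years_undiscounted`,
#'   plus `qalys_undiscounted`.
#' @export
accrue <- function(trace, arm, utilities, disutility_on = TRUE,
                   apply_rdi = FALSE, half_cycle = FALSE) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(arm, "arm_config"),
            inherits(utilities, "utility_set"))
  h <- nrow(trace) - 1L
  i <- seq_len(h) + 1L # rows for cycles 1..h
  pre <- trace$pre[i]
  post <- trace$post[i]
  if (half_cycle) {
    pre <- (trace$pre[i - 1L] + pre) / 2
    post <- (trace$post[i - 1L] + post) / 2
  }
  deaths <- trace$new_deaths[i]
  df_c <- trace$df_cost[i]
  df_o <- trace$df_out[i]

  cc <- arm$pre_progression_cycle_costs
  drug <- cc$drug_acquisition *
    if (apply_rdi) arm$relative_dose_intensity else 1
  tx_admin <- drug + cc$administration
  background <- cc$pretreatment + cc$lab_tests + cc$monitoring + cc$prophylaxis
  ae <- ae_one_off(arm)

  costs <- list(
    treatment_and_administration = sum(pre * tx_admin * df_c),
    ae = ae$cost,
    pre_progression_background = sum(pre * background * df_c),
    post_progression_background =
      sum(post * arm$post_progression_cycle_cost * df_c),
    terminal_care = sum(deaths * arm$end_of_life_cost * df_c)
  )
  costs$total <- costs$treatment_and_administration + costs$ae +
    costs$pre_progression_background + costs$post_progression_background +
    costs$terminal_care

  ae_dec <- if (disutility_on) ae$qaly_decrement else 0
  q_pre <- sum(pre * utilities$u_pre / 12 * df_o) + ae_dec
  q_post <- sum(post * utilities$u_post / 12 * df_o)
  qu_pre <- sum(pre * utilities$u_pre / 12) + ae_dec
  qu_post <- sum(post * utilities$u_post / 12)
  ly_pre <- sum(pre / 12 * df_o)
  ly_post <- sum(post / 12 * df_o)
  lyu_pre <- sum(pre / 12)
  lyu_post <- sum(post / 12)

  structure(
    list(
      arm_id = arm$arm_id,
      horizon = h,
      costs = costs,
      qalys = list(pre = q_pre, post = q_post, total = q_pre + q_post),
      qalys_undiscounted = list(pre = qu_pre, post = qu_post,
                                total = qu_pre + qu_post),
      life_years = list(pre = ly_pre, post = ly_post,
                        total = ly_pre + ly_post),
      life_years_undiscounted = list(pre = lyu_pre, post = lyu_post,
                                     total = lyu_pre + lyu_post)
    ),
    class = "arm_result"
  )
}

#' Assemble an arm result from externally computed components
#'
#' Builds an `arm_result` directly from component values (e.g. the rows of
#' a published results table) so that the incremental-analysis stage can be
#' exercised on printed inputs without rerunning the trace.
#'
#' @param arm_id Arm identifier.
#' @param costs Named list/vector with the five cost components
#'   `treatment_and_administration`, `ae`, `pre_progression_background`,
#'   `post_progression_background`, `terminal_care` (euros, discounted).
#' @param qalys_pre,qalys_post Discounted QALYs by state.
#' @param ly_pre,ly_post Discounted life years by state.
#' @param ly_pre_undisc,ly_post_undisc Undiscounted life years by state.
#' @param horizon Model horizon in months (bookkeeping only).
#' @return An object of class `arm_result` with `total` fields computed as
#'   the sums of the supplied components.
#' @export
arm_result_from_components <- function(arm_id, costs, qalys_pre, qalys_post,
                                       ly_pre = NA_real_, ly_post = NA_real_,
                                       ly_pre_undisc = NA_real_,
                                       ly_post_undisc = NA_real_,
                                       horizon = NA_integer_) {
  costs <- as.list(costs)
  need <- c("treatment_and_administration", "ae", "pre_progression_background",
            "post_progression_background", "terminal_care")
  missing <- setdiff(need, names(costs))
  if (length(missing)) {
    stop("cost component(s) missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  costs <- costs[need]
  costs$total <- sum(unlist(costs))
  structure(
    list(arm_id = arm_id, horizon = horizon, costs = costs,
         qalys = list(pre = qalys_pre, post = qalys_post,
                      total = qalys_pre + qalys_post),
         qalys_undiscounted = list(pre = NA_real_, post = NA_real_,
                                   total = NA_real_),
         life_years = list(pre = ly_pre, post = ly_post,
                           total = ly_pre + ly_post),
         life_years_undiscounted = list(pre = ly_pre_undisc,
                                        post = ly_post_undisc,
                                        total = ly_pre_undisc + ly_post_undisc)),
    class = "arm_result"
  )
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("<arm_result> %s\n", x$arm_id))
  cat(sprintf("  total cost  %12s EUR\n",
              format(round_half_up(x$costs$total), big.mark = ",")))
  cat(sprintf("  total QALYs %12.3f\n", x$qalys$total))
  if (!is.na(x$life_years$total)) {
    cat(sprintf("  total LYs   %12.3f discounted / %.3f undiscounted\n",
                x$life_years$total, x$life_years_undiscounted$total))
  }
  invisible(x)
}
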