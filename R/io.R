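#' Validate (and coerce) a pseudo individual-patient data table
#'
#' @param ipd Data frame with columns `time_months` (strictly positive) and
#'   `event` (1 = event observed, 0 = right-censored); a column named
#'   `time` is accepted as an alias for `time_months`.
#' @return The table with class `ipd_table`.
#' @export
validate_ipd <- function(ipd) {
  ipd <- as.data.frame(ipd)
  if ("time" %in% names(ipd) && !("time_months" %in% names(ipd))) {
    names(ipd)[names(ipd) == "time"] <- "time_months"
  }
  missing <- setdiff(c("time_months", "event"), names(ipd))
  if (length(missing)) {
    stop("IPD table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(ipd) < 2L) stop("IPD table needs at least 2 records", call. = FALSE)
  if (any(!is.finite(ipd$time_months)) || any(ipd$time_months <= 0)) {
    stop("all IPD times must be finite and strictly positive", call. = FALSE)
  }
  if (!all(ipd$event %in% c(0, 1))) {
    stop("IPD event flag must be 0 (censored) or 1 (event)", call. = FALSE)
  }
  structure(ipd[, c("time_months", "event")],
            class = c("ipd_table", "data.frame"))
}

#' Read / write pseudo individual-patient data
#'
#' Two-column delimited text (`time_months`, `event`), header row required,
#' '.' decimal separator.
#'
#' @param path File path.
#' @param ipd An IPD table.
#' @return `read_ipd`: an `ipd_table`; `write_ipd`: `path`, invisibly.
#' @export
read_ipd <- function(path) {
  if (!file.exists(path)) stop("IPD file not found: ", path, call. = FALSE)
  validate_ipd(utils::read.csv(path))
}

#' @rdname read_ipd
#' @export
write_ipd <- function(ipd, path) {
  ipd <- validate_ipd(ipd)
  utils::write.csv(as.data.frame(ipd), path, row.names = FALSE)
  invisible(path)
}

#' Load a model configuration from a YAML file
#'
#' The schema mirrors [model_config()]: top-level keys `arms` (sequence of
#' arm mappings), `utilities`, `annual_discount_rate`, `cycle_length`,
#' `horizon`, `wtp_threshold`, `survival_spec`, `scenario_flags`. Per-arm
#' hazard-ratio chains are sequences of `{label, hr}` mappings. A survival
#' endpoint may point to a pseudo-IPD file via `ipd_path` (relative paths
#' resolve against the config file's directory); the table is read and
#' attached at load time. Missing optional keys take the documented
#' defaults; a missing required key is a schema error naming the key; every
#' typed invariant is checked before the configuration is returned.
#'
#' @param path Path to the YAML configuration.
#' @return A validated [model_config].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  for (key in c("arms", "survival_spec")) {
    if (is.null(raw[[key]])) {
      stop("config schema error: required field '", key, "' is missing",
           call. = FALSE)
    }
  }
  arms <- lapply(raw$arms, parse_arm)
  utilities <- if (is.null(raw$utilities)) utility_set() else
    utility_set(required_field(raw$utilities, "u_pre", "utilities"),
                required_field(raw$utilities, "u_post", "utilities"))
  sspec <- raw$survival_spec
  for (ep in intersect(c("PFS", "OS"), names(sspec))) {
    if (!is.null(sspec[[ep]]$ipd_path)) {
      p <- sspec[[ep]]$ipd_path
      if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(dirname(path), p)
      sspec[[ep]]$ipd <- read_ipd(p)
    }
  }
  cfg <- model_config(
    arms = arms,
    utilities = utilities,
    annual_discount_rate = raw$annual_discount_rate %||% 0.035,
    cycle_length = raw$cycle_length %||% 1,
    horizon = raw$horizon %||% 180,
    wtp_threshold = raw$wtp_threshold %||% 36000,
    survival_spec = sspec,
    scenario_flags = raw$scenario_flags %||% list()
  )
  if (!is.null(raw$reference_arm_id) &&
      !identical(raw$reference_arm_id, cfg$reference_arm_id)) {
    stop("reference_arm_id '", raw$reference_arm_id,
         "' disagrees with the arm flagged reference", call. = FALSE)
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

required_field <- function(x, field, where) {
  if (is.null(x[[field]])) {
    stop("config schema error: required field '", where, ".", field,
         "' is missing", call. = FALSE)
  }
  x[[field]]
}

parse_arm <- function(a) {
  arm_config(
    arm_id = required_field(a, "arm_id", "arms[]"),
    pre_progression_cycle_costs =
      required_field(a, "pre_progression_cycle_costs", "arms[]"),
    relative_dose_intensity = a$relative_dose_intensity %||% 1,
    post_progression_cycle_cost = a$post_progression_cycle_cost %||% 1057.41,
    end_of_life_cost = a$end_of_life_cost %||% 823.60,
    ae_profile = if (is.null(a$ae_profile)) NULL else
      do.call(rbind, lapply(a$ae_profile, as.data.frame)),
    hr_pfs = parse_chain(a$hr_pfs),
    hr_os = parse_chain(a$hr_os),
    reference = isTRUE(a$reference)
  )
}

parse_chain <- function(links) {
  if (is.null(links)) return(hr_chain(1, "reference"))
  hr_chain(vapply(links, function(l) as.numeric(l$hr), numeric(1)),
           vapply(links, function(l) as.character(l$label %||% "link"),
                  character(1)))
}

#' Save a model configuration as YAML
#'
#' Writes the schema read by [load_config()]; a fitted survival curve
#' frozen into the configuration with [freeze_fit()] round-trips through
#' this writer.
#'
#' @param config A [model_config].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_config <- function(config, path) {
  config <- validate_model_config(config)
  ser_chain <- function(ch) lapply(ch$links, function(l)
    list(label = l$label, hr = l$hr))
  raw <- list(
    reference_arm_id = config$reference_arm_id,
    annual_discount_rate = config$annual_discount_rate,
    cycle_length = config$cycle_length,
    horizon = config$horizon,
    wtp_threshold = config$wtp_threshold,
    utilities = list(u_pre = config$utilities$u_pre,
                     u_post = config$utilities$u_post),
    survival_spec = lapply(config$survival_spec, function(sp) {
      out <- list(family = sp[["family"]])
      if (!is.null(sp[["params"]])) out$params <- as.list(sp[["params"]])
      if (!is.null(sp[["ipd_path"]])) out$ipd_path <- sp[["ipd_path"]]
      if (!is.null(sp$hazard_multiplier) && sp$hazard_multiplier != 1) {
        out$hazard_multiplier <- sp$hazard_multiplier
      }
      if (!is.null(sp$alt_params)) out$alt_params <- sp$alt_params
      out
    }),
    scenario_flags = config$scenario_flags,
    arms = lapply(unname(config$arms), function(a) {
      out <- list(
        arm_id = a$arm_id,
        reference = a$reference,
        relative_dose_intensity = a$relative_dose_intensity,
        pre_progression_cycle_costs = a$pre_progression_cycle_costs,
        post_progression_cycle_cost = a$post_progression_cycle_cost,
        end_of_life_cost = a$end_of_life_cost,
        hr_pfs = ser_chain(a$hr_pfs),
        hr_os = ser_chain(a$hr_os)
      )
      if (nrow(a$ae_profile)) {
        out$ae_profile <- lapply(seq_len(nrow(a$ae_profile)), function(i)
          as.list(a$ae_profile[i, ]))
      }
      out
    })
  )
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' Freeze a fitted survival curve into a configuration
#'
#' Replaces an endpoint's specification with the declared parameters of a
#' fit, so the fit can be reused without refitting (and serialized via
#' [save_config()]).
#'
#' @param config A [model_config].
#' @param endpoint `"PFS"` or `"OS"`.
#' @param fit A [fit_parametric()] result (or a [parametric_survival]).
#' @return The updated, revalidated configuration.
#' @export
freeze_fit <- function(config, endpoint = c("PFS", "OS"), fit) {
  endpoint <- match.arg(endpoint)
  curve <- if (inherits(fit, "fit_result")) fit$curve else fit
  stopifnot(inherits(curve, "parametric_survival"))
  sp <- config$survival_spec[[endpoint]]
  sp[["family"]] <- curve$family
  sp[["params"]] <- curve$params
  sp[["ipd"]] <- NULL
  sp[["ipd_path"]] <- NULL
  config$survival_spec[[endpoint]] <- sp
  validate_model_config(config)
}

#' Write deterministic results as delimited text
#'
#' One row per (arm, metric) mirroring the published results-table
#' structure — the five cost components and total, QALYs by state,
#' discounted and undiscounted life years — followed by an incremental
#' block per comparison (delta cost, delta effect, ICER where defined, and
#' the dominance label). Euros are written with 2 decimals, QALYs and life
#' years with 3; the `text` column carries dominance labels.
#'
#' @param results A [run_model()] result (class `cea_results`).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(results, path) {
  if (is.null(results$arm_results) || length(results$arm_results) == 0L) {
    stop("no results to write", call. = FALSE)
  }
  rows <- list()
  for (ar in results$arm_results) {
    num <- c(
      cost_treatment_and_administration = ar$costs$treatment_and_administration,
      cost_ae = ar$costs$ae,
      cost_pre_progression_background = ar$costs$pre_progression_background,
      cost_post_progression_background = ar$costs$post_progression_background,
      cost_terminal_care = ar$costs$terminal_care,
      cost_total = ar$costs$total
    )
    num <- round_half_up(num, 2)
    q <- round_half_up(c(
      qalys_pre = ar$qalys$pre, qalys_post = ar$qalys$post,
      qalys_total = ar$qalys$total,
      ly_pre = ar$life_years$pre, ly_post = ar$life_years$post,
      ly_total = ar$life_years$total,
      ly_pre_undiscounted = ar$life_years_undiscounted$pre,
      ly_post_undiscounted = ar$life_years_undiscounted$post,
      ly_total_undiscounted = ar$life_years_undiscounted$total
    ), 3)
    v <- c(num, q)
    rows[[length(rows) + 1L]] <- data.frame(
      section = "arm", id = ar$arm_id, metric = names(v), value = unname(v),
      text = "", stringsAsFactors = FALSE)
  }
  for (inc in results$incrementals) {
    id <- paste0(inc$comparator_pair[1], "_vs_", inc$comparator_pair[2],
                 "_", inc$effect_measure)
    v <- c(delta_cost = round_half_up(inc$delta_cost, 2),
           delta_effect = round_half_up(inc$delta_effect, 3),
           icer = if (is.na(inc$icer)) NA_real_ else
             round_half_up(inc$icer, 2))
    rows[[length(rows) + 1L]] <- data.frame(
      section = "incremental", id = id,
      metric = c(names(v), "label"),
      value = c(unname(v), NA_real_),
      text = c("", "", "", inc$label), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read back a results file written by [write_results()]
#'
#' @param path Path to the CSV file.
#' @return Data frame with columns `section`, `id`, `metric`, `value`,
#'   `text`.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("results file not found: ", path,
                               call. = FALSE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(section = "character",
                                        id = "character",
                                        metric = "character",
                                        value = "numeric",
                                        text = "character"))
  out$text[is.na(out$text)] <- ""
  out
}
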