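#' @importFrom stats rbeta rgamma rlnorm
NULL

#' Declare an uncertain parameter for probabilistic sensitivity analysis
#'
#' Each uncertain input is assigned a distribution by measurement scale:
#' beta for utilities (bounded in `[0, 1]`), gamma for costs
#' (non-negative), lognormal for hazard ratios and other positive
#' effect ratios. Dispersion is given either as a standard error on the
#' natural scale (`dispersion_type = "sd"`) or a coefficient of variation
#' (`"cv"`).
#'
#' @param path Dotted configuration path of the parameter (see
#'   [config_set()]).
#' @param family `"beta"`, `"gamma"` or `"lognormal"`.
#' @param central Central (mean) value, in the family's support.
#' @param dispersion Standard error or CV, `>= 0` (0 = parameter held
#'   fixed).
#' @param dispersion_type `"sd"` or `"cv"`.
#' @return An object of class `uncertain_parameter`.
#' @export
uncertain_parameter <- function(path, family = c("beta", "gamma", "lognormal"),
                                central, dispersion,
                                dispersion_type = c("sd", "cv")) {
  family <- match.arg(family)
  dispersion_type <- match.arg(dispersion_type)
  stop_if_not_number(dispersion, "dispersion", lower = 0)
  switch(family,
    beta = stop_if_not_number(central, "beta central value", 0, 1),
    gamma = stop_if_not_number(central, "gamma central value", lower = 0),
    lognormal = stop_if_not_number(central, "lognormal central value",
                                   lower = 0, open_lower = TRUE)
  )
  structure(list(path = path, family = family, central = central,
                 dispersion = dispersion, dispersion_type = dispersion_type),
            class = "uncertain_parameter")
}

#' Moment-match distribution parameters from mean and standard deviation
#'
#' Closed-form inversion of the first two moments: beta
#' (`alpha = m * (m * (1 - m) / v - 1)`, `beta = (1 - m) * (...)`),
#' gamma (`shape = m^2 / v`, `rate = m / v`) and lognormal on the natural
#' scale (`sigma^2 = log(1 + v / m^2)`, `mu = log(m) - sigma^2 / 2`).
#'
#' @param family `"beta"`, `"gamma"` or `"lognormal"`.
#' @param mean Target mean, in the family's support.
#' @param sd Target standard deviation, > 0.
#' @return Named list of distribution parameters.
#' @export
#' @examples
#' moment_match("beta", 0.5, 0.1) # alpha = beta = 12
moment_match <- function(family = c("beta", "gamma", "lognormal"), mean, sd) {
  family <- match.arg(family)
  stop_if_not_number(sd, "sd", lower = 0, open_lower = TRUE)
  v <- sd^2
  switch(family,
    beta = {
      stop_if_not_number(mean, "beta mean", 0, 1,
                         open_lower = TRUE, open_upper = TRUE)
      if (v >= mean * (1 - mean)) {
        stop("infeasible beta variance: need sd^2 < mean * (1 - mean) = ",
             signif(mean * (1 - mean), 4), call. = FALSE)
      }
      k <- mean * (1 - mean) / v - 1
      list(alpha = mean * k, beta = (1 - mean) * k)
    },
    gamma = {
      stop_if_not_number(mean, "gamma mean", lower = 0, open_lower = TRUE)
      list(shape = mean^2 / v, rate = mean / v)
    },
    lognormal = {
      stop_if_not_number(mean, "lognormal mean", lower = 0, open_lower = TRUE)
      s2 <- log(1 + v / mean^2)
      list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
    }
  )
}

sample_uncertain <- function(u, n = 1L) {
  sd <- if (u$dispersion_type == "cv") u$dispersion * u$central else
    u$dispersion
  if (sd == 0 || u$central == 0 ||
      (u$family == "beta" && (u$central == 1))) {
    return(rep(u$central, n))
  }
  p <- moment_match(u$family, u$central, sd)
  switch(u$family,
    beta = rbeta(n, p$alpha, p$beta),
    gamma = rgamma(n, shape = p$shape, rate = p$rate),
    lognormal = rlnorm(n, p$meanlog, p$sdlog)
  )
}

#' Default uncertain-parameter set for a configuration
#'
#' Every cost input (gamma, CV 20\%), both utilities (beta, SE 0.05) and
#' every hazard-ratio link of the comparator arms (lognormal, CV 20\%).
#' These defaults are conventional placeholders — the dispersions should be
#' replaced with study-specific standard errors whenever available.
#'
#' @param config A [model_config].
#' @param cost_cv CV for cost parameters.
#' @param utility_se Standard error for utilities.
#' @param hr_cv CV for hazard-ratio links.
#' @return List of [uncertain_parameter]s.
#' @export
default_uncertain_parameters <- function(config, cost_cv = 0.20,
                                         utility_se = 0.05, hr_cv = 0.20) {
  config <- validate_model_config(config)
  out <- list()
  add <- function(path, family, central, dispersion, type) {
    out[[length(out) + 1L]] <<-
      uncertain_parameter(path, family, central, dispersion, type)
  }
  add("utilities.u_pre", "beta", config$utilities$u_pre, utility_se, "sd")
  add("utilities.u_post", "beta", config$utilities$u_post, utility_se, "sd")
  for (id in names(config$arms)) {
    arm <- config$arms[[id]]
    base <- paste0("arms.", id, ".")
    for (comp in PRE_COST_COMPONENTS) {
      central <- arm$pre_progression_cycle_costs[[comp]]
      if (central > 0) {
        add(paste0(base, "pre_progression_cycle_costs.", comp),
            "gamma", central, cost_cv, "cv")
      }
    }
    add(paste0(base, "post_progression_cycle_cost"), "gamma",
        arm$post_progression_cycle_cost, cost_cv, "cv")
    add(paste0(base, "end_of_life_cost"), "gamma",
        arm$end_of_life_cost, cost_cv, "cv")
    if (!arm$reference) {
      for (ep in c("hr_pfs", "hr_os")) {
        links <- arm[[ep]]$links
        for (i in seq_along(links)) {
          add(paste0(base, ep, ".links.", i, ".hr"),
              "lognormal", links[[i]]$hr, hr_cv, "cv")
        }
      }
    }
  }
  out
}

#' Probabilistic sensitivity analysis by Monte-Carlo simulation
#'
#' For each draw, every uncertain parameter is sampled independently from
#' its moment-matched distribution, the sampled values are written into the
#' configuration, and the full deterministic pipeline is rerun; per-arm
#' total discounted cost and QALYs are recorded. The run is fully
#' reproducible given `(seed, n_draws, config)`; the caller's RNG state is
#' left untouched. Draws whose pipeline fails (e.g. a sampled utility pair
#' violating `u_post <= u_pre`) are excluded and counted; more than 1\% of
#' failures aborts the run.
#'
#' @param config A [model_config].
#' @param uncertain List of [uncertain_parameter]s; defaults to
#'   [default_uncertain_parameters()].
#' @param n_draws Number of Monte-Carlo draws, `>= 1`.
#' @param seed Integer seed.
#' @return An object of class `psa_draws`: `draws` (data frame with
#'   columns `draw`, `arm_id`, `cost`, `qalys`), `n_draws`, `seed`,
#'   `n_failed`, `arm_ids`, `reference_arm_id`.
#' @export
run_psa <- function(config, uncertain = default_uncertain_parameters(config),
                    n_draws = 1000, seed = 1L) {
  config <- validate_model_config(config)
  stop_if_not_number(n_draws, "n_draws", lower = 1)
  n_draws <- as.integer(n_draws)
  stopifnot(all(vapply(uncertain, inherits, logical(1),
                       "uncertain_parameter")))
  arm_ids <- names(config$arms)
  rows <- vector("list", n_draws)
  n_failed <- 0L
  local_seed(seed, {
    for (d in seq_len(n_draws)) {
      cfg <- config
      ok <- TRUE
      res <- tryCatch({
        for (u in uncertain) {
          cfg <- config_set(cfg, u$path, sample_uncertain(u))
        }
        suppressWarnings(run_model(cfg, validate = TRUE))
      }, error = function(e) {
        ok <<- FALSE
        NULL
      })
      if (!ok) {
        n_failed <- n_failed + 1L
        next
      }
      rows[[d]] <- data.frame(
        draw = d,
        arm_id = arm_ids,
        cost = vapply(res$arm_results[arm_ids],
                      function(a) a$costs$total, numeric(1)),
        qalys = vapply(res$arm_results[arm_ids],
                       function(a) a$qalys$total, numeric(1)),
        stringsAsFactors = FALSE)
    }
  })
  if (n_failed > 0.01 * n_draws) {
    stop(n_failed, " of ", n_draws, " PSA draws failed (> 1%); ",
         "check the uncertain-parameter specification", call. = FALSE)
  }
  structure(
    list(draws = do.call(rbind, rows), n_draws = n_draws, seed = seed,
         n_failed = n_failed, arm_ids = arm_ids,
         reference_arm_id = config$reference_arm_id),
    class = "psa_draws"
  )
}

#' @export
print.psa_draws <- function(x, ...) {
  cat(sprintf("<psa_draws> %d draws (seed %d, %d failed), arms: %s\n",
              x$n_draws, x$seed, x$n_failed,
              paste(x$arm_ids, collapse = ", ")))
  invisible(x)
}

psa_pair <- function(draws, pair) {
  stopifnot(inherits(draws, "psa_draws"), length(pair) == 2L)
  miss <- setdiff(pair, draws$arm_ids)
  if (length(miss)) {
    stop("arm(s) not present in the PSA draws: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  d <- draws$draws
  a <- d[d$arm_id == pair[1], ][order(d$draw[d$arm_id == pair[1]]), ]
  b <- d[d$arm_id == pair[2], ][order(d$draw[d$arm_id == pair[2]]), ]
  stopifnot(identical(a$draw, b$draw))
  data.frame(draw = a$draw,
             delta_cost = a$cost - b$cost,
             delta_qalys = a$qalys - b$qalys)
}

#' Per-draw incremental scatter (cost-effectiveness plane)
#'
#' @param draws A [run_psa()] result.
#' @param pair Character vector `c(intervention, comparator)`.
#' @return Data frame with columns `draw`, `delta_cost`, `delta_qalys`,
#'   suitable for export as delimited text or plotting.
#' @export
psa_scatter <- function(draws, pair) psa_pair(draws, pair)

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the probability that the intervention
#' is cost-effective is the fraction of draws with strictly positive
#' incremental net monetary benefit,
#' `wtp * delta_QALYs - delta_cost > 0` (ties count as not
#' cost-effective). The curve is a deterministic function of the draws; no
#' resampling occurs here.
#'
#' @param draws A [run_psa()] result.
#' @param pair Character vector `c(intervention, comparator)`.
#' @param wtp_grid Willingness-to-pay grid in euros; the default runs 0 to
#'   100,000 in steps of 1,000 (and therefore includes 36,000).
#' @return Data frame with columns `wtp` and `probability` (in `[0, 1]`).
#' @export
ceac <- function(draws, pair, wtp_grid = seq(0, 100000, by = 1000)) {
  if (length(wtp_grid) < 1L) stop("empty WTP grid", call. = FALSE)
  inc <- psa_pair(draws, pair)
  prob <- vapply(wtp_grid, function(w)
    mean(w * inc$delta_qalys - inc$delta_cost > 0), numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}
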