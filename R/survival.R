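#' @importFrom stats setNames uniroot optim qweibull qlogis runif
NULL

SURV_FAMILIES <- c("exponential", "weibull", "gompertz", "loglogistic")

FAMILY_PARS <- list(
  exponential = "rate",
  weibull     = c("shape", "scale"),
  gompertz    = c("shape", "rate"),
  loglogistic = c("shape", "scale")
)

#' Construct a parametric survival curve
#'
#' Represents a declared (or fitted) parametric survival distribution used to
#' extrapolate progression-free survival (PFS) or overall survival (OS)
#' beyond trial follow-up. Time is measured in months throughout.
#'
#' Supported families and their survival functions:
#' \describe{
#'   \item{exponential}{`S(t) = exp(-rate * t)`}
#'   \item{weibull}{`S(t) = exp(-(t/scale)^shape)`}
#'   \item{gompertz}{`S(t) = exp(-(rate/shape) * (exp(shape*t) - 1))`}
#'   \item{loglogistic}{`S(t) = 1 / (1 + (t/scale)^shape)`}
#' }
#' All parameters must be strictly positive. A Gompertz shape <= 0 is
#' rejected: it implies a non-zero cure fraction, incompatible with a
#' lifetime-horizon model in metastatic disease where the whole cohort must
#' eventually die.
#'
#' @param family One of `"exponential"`, `"weibull"`, `"gompertz"`,
#'   `"loglogistic"`.
#' @param params Named numeric vector/list of family parameters (see above).
#' @param endpoint Endpoint label, `"PFS"` or `"OS"`.
#' @return An object of class `parametric_survival`.
#' @export
#' @examples
#' pfs <- parametric_survival("weibull", c(shape = 1.3, scale = 10), "PFS")
#' survival_at(pfs, c(0, 6, 12))
parametric_survival <- function(family, params, endpoint = c("PFS", "OS")) {
  family <- match.arg(family, SURV_FAMILIES)
  endpoint <- match.arg(endpoint)
  params <- unlist(params)
  need <- FAMILY_PARS[[family]]
  if (!all(need %in% names(params))) {
    stop("family '", family, "' needs parameters: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  params <- params[need]
  for (p in need) {
    stop_if_not_number(params[[p]], paste0(family, " ", p),
                       lower = 0, open_lower = TRUE)
  }
  structure(
    list(family = family, params = as.list(params), endpoint = endpoint),
    class = "parametric_survival"
  )
}

#' Evaluate a survival function
#'
#' Generic evaluation S(t) for every curve representation in the package:
#' declared parametric curves, proportional-hazards transforms and
#' consistency-clamped PFS curves.
#'
#' @param curve A survival-curve object.
#' @param t Vector of times in months, all `>= 0`.
#' @return Survival probabilities in `[0, 1]`, same length as `t`.
#' @export
survival_at <- function(curve, t) {
  if (any(t < 0)) stop("survival requested at negative time", call. = FALSE)
  UseMethod("survival_at")
}

#' @export
survival_at.parametric_survival <- function(curve, t) {
  p <- curve$params
  switch(curve$family,
    exponential = exp(-p$rate * t),
    weibull     = exp(-(t / p$scale)^p$shape),
    gompertz    = exp(-(p$rate / p$shape) * (exp(p$shape * t) - 1)),
    loglogistic = 1 / (1 + (t / p$scale)^p$shape)
  )
}

#' @export
survival_at.ph_survival <- function(curve, t) {
  survival_at(curve$base, t)^curve$hr
}

#' @export
survival_at.clamped_survival <- function(curve, t) {
  pmin(survival_at(curve$pfs, t), survival_at(curve$os, t))
}

#' @export
print.parametric_survival <- function(x, ...) {
  cat(sprintf("<parametric_survival> %s %s(%s)\n", x$endpoint, x$family,
              paste(sprintf("%s=%.4g", names(x$params),
                            unlist(x$params)), collapse = ", ")))
  invisible(x)
}

#' Median survival time
#'
#' Closed form where the family admits one, otherwise numeric root-finding
#' on `S(t) = 1/2`.
#'
#' @param curve A survival-curve object.
#' @return Median time in months.
#' @export
surv_median <- function(curve) UseMethod("surv_median")

#' @export
surv_median.parametric_survival <- function(curve) {
  p <- curve$params
  switch(curve$family,
    exponential = log(2) / p$rate,
    weibull     = p$scale * log(2)^(1 / p$shape),
    loglogistic = p$scale, # S(scale) = 1/2 by construction
    gompertz    = log(1 + p$shape * log(2) / p$rate) / p$shape
  )
}

#' @export
surv_median.default <- function(curve) {
  upper <- 1
  while (survival_at(curve, upper) > 0.5 && upper < 1e7) upper <- upper * 2
  uniroot(function(t) survival_at(curve, t) - 0.5,
          lower = 0, upper = upper, tol = 1e-10)$root
}

#' Hazard-ratio chain for indirect treatment comparison
#'
#' In the absence of head-to-head trials, the comparator's hazard is related
#' to the reference arm's through a chain of published hazard ratios (an
#' indirect comparison). Under proportional hazards the links multiply into
#' a single combined HR.
#'
#' @param hr Numeric vector of link hazard ratios, all `> 0`.
#' @param labels Optional character labels, one per link.
#' @return An object of class `hr_chain` with fields `links` and
#'   `combined_hr` (the product of link HRs).
#' @export
#' @examples
#' hr_chain(c(1.25, 0.80), c("trial A vs B", "trial B vs C"))
hr_chain <- function(hr, labels = NULL) {
  hr <- as.numeric(hr)
  if (length(hr) < 1L || any(!is.finite(hr)) || any(hr <= 0)) {
    stop("all hazard ratios in a chain must be finite and > 0", call. = FALSE)
  }
  if (is.null(labels)) labels <- paste0("link", seq_along(hr))
  if (length(labels) != length(hr)) {
    stop("one label per hazard ratio required", call. = FALSE)
  }
  links <- lapply(seq_along(hr), function(i) list(label = labels[i], hr = hr[i]))
  structure(list(links = links, combined_hr = prod(hr)), class = "hr_chain")
}

#' Combined hazard ratio of a chain
#'
#' Recomputed as the product of the link HRs (robust to sensitivity
#' analyses mutating individual links in place).
#'
#' @param chain An `hr_chain`.
#' @return Positive scalar.
#' @export
combined_hr <- function(chain) {
  prod(vapply(chain$links, function(l) l$hr, numeric(1)))
}

#' Apply a hazard-ratio chain to a survival curve
#'
#' Proportional-hazards transform `S_new(t) = S_base(t)^HR`. For families
#' closed under proportional hazards (exponential, Weibull, Gompertz) the
#' result is returned in-family with transformed parameters; otherwise a
#' generic power-transformed curve is returned.
#'
#' @param base A survival-curve object.
#' @param chain An [hr_chain] (or a single positive number).
#' @return A survival-curve object.
#' @export
#' @examples
#' os <- parametric_survival("exponential", c(rate = 0.05), "OS")
#' os2 <- apply_hazard_ratio(os, hr_chain(2))
#' surv_median(os2) # half the base median
apply_hazard_ratio <- function(base, chain) {
  hr <- if (inherits(chain, "hr_chain")) combined_hr(chain) else as.numeric(chain)
  if (!is.finite(hr) || hr <= 0) {
    stop("combined hazard ratio must be finite and > 0", call. = FALSE)
  }
  if (inherits(base, "parametric_survival")) {
    p <- base$params
    out <- switch(base$family,
      exponential = parametric_survival("exponential",
        c(rate = p$rate * hr), base$endpoint),
      weibull = parametric_survival("weibull",
        c(shape = p$shape, scale = p$scale * hr^(-1 / p$shape)), base$endpoint),
      gompertz = parametric_survival("gompertz",
        c(shape = p$shape, rate = p$rate * hr), base$endpoint),
      NULL
    )
    if (!is.null(out)) return(out)
  }
  structure(list(base = base, hr = hr), class = "ph_survival")
}

#' Clamp a PFS curve to lie at or below an OS curve
#'
#' Progression precedes or coincides with death, so PFS(t) <= OS(t) must
#' hold at every time point; independent hazard-ratio chains on the two
#' endpoints can otherwise cross the curves. The clamp is point-wise:
#' `PFS(t) <- min(PFS(t), OS(t))`.
#'
#' @param pfs,os Survival-curve objects.
#' @return A curve object evaluating the clamped PFS.
#' @export
clamp_pfs <- function(pfs, os) {
  structure(list(pfs = pfs, os = os), class = "clamped_survival")
}

#' Fit a parametric survival family to pseudo individual-patient data
#'
#' Maximum-likelihood fit under right censoring
#' (log-likelihood = sum over events of log f(t_i) + sum over censored of
#' log S(t_i)), via [flexsurv::flexsurvreg()] with its deterministic,
#' data-derived starting values, so repeated fits on the same data are
#' identical.
#'
#' @param ipd An IPD table: data frame with columns `time_months` (> 0) and
#'   `event` (1 = event observed, 0 = right-censored).
#' @param family Distribution family, as in [parametric_survival()].
#' @param endpoint Endpoint label attached to the fitted curve.
#' @return An object of class `fit_result`: fields `curve`
#'   ([parametric_survival]), `log_likelihood`, `aic`, `bic`, `n_events`,
#'   `n_censored`, `n_params`.
#' @export
fit_parametric <- function(ipd, family, endpoint = c("PFS", "OS")) {
  family <- match.arg(family, SURV_FAMILIES)
  endpoint <- match.arg(endpoint)
  ipd <- validate_ipd(ipd)
  if (sum(ipd$event) < 2L) {
    stop("at least 2 observed events are required to fit a survival model",
         call. = FALSE)
  }
  dist <- c(exponential = "exp", weibull = "weibull",
            gompertz = "gompertz", loglogistic = "llogis")[[family]]
  fit <- tryCatch(
    flexsurv::flexsurvreg(
      survival::Surv(time_months, event) ~ 1,
      data = ipd, dist = dist
    ),
    error = function(e) {
      stop("survival fit (", family, ") failed to converge: ",
           conditionMessage(e), call. = FALSE)
    }
  )
  est <- fit$res[, "est"]
  params <- setNames(as.numeric(est), rownames(fit$res))
  if (family == "gompertz" && params[["shape"]] <= 0) {
    stop("Gompertz fit produced shape <= 0 (implied cure fraction); ",
         "this family is restricted to shape > 0 so that S(t) -> 0",
         call. = FALSE)
  }
  ll <- as.numeric(fit$loglik)
  k <- fit$npars
  n <- nrow(ipd)
  structure(
    list(
      curve = parametric_survival(family, params, endpoint),
      log_likelihood = ll,
      aic = 2 * k - 2 * ll,
      bic = k * log(n) - 2 * ll,
      n_events = sum(ipd$event),
      n_censored = sum(ipd$event == 0),
      n_params = k
    ),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s %s: logLik %.2f, AIC %.2f, BIC %.2f (%d events, %d censored)\n",
              x$curve$endpoint, x$curve$family, x$log_likelihood, x$aic,
              x$bic, x$n_events, x$n_censored))
  print(x$curve)
  invisible(x)
}

#' Exponential curve matched to a landmark survival probability
#'
#' "Endpoint" fitting mode for the exponential family: instead of a
#' maximum-likelihood fit to the full follow-up ("curve" mode, see
#' [fit_parametric()]), the rate is solved from a single reported landmark,
#' `rate = -log(S*) / t*`.
#'
#' @param surv_prob Survival probability at the landmark, in (0, 1).
#' @param t_landmark Landmark time in months, > 0.
#' @param endpoint Endpoint label.
#' @return A [parametric_survival] of family `"exponential"`.
#' @export
exponential_endpoint <- function(surv_prob, t_landmark,
                                 endpoint = c("PFS", "OS")) {
  stop_if_not_number(surv_prob, "landmark survival probability",
                     lower = 0, upper = 1, open_lower = TRUE, open_upper = TRUE)
  stop_if_not_number(t_landmark, "landmark time", lower = 0, open_lower = TRUE)
  parametric_survival("exponential",
                      c(rate = -log(surv_prob) / t_landmark),
                      match.arg(endpoint))
}

#' Select the best-fitting parametric family
#'
#' Minimum-AIC selection among fits of the same data; ties broken first by
#' fewer parameters (parsimony), then by a fixed family order
#' (exponential, Weibull, Gompertz, log-logistic).
#'
#' @param fits List of [fit_parametric()] results on identical data.
#' @return The selected `fit_result`.
#' @export
select_best_fit <- function(fits) {
  if (length(fits) < 1L) stop("no fits supplied", call. = FALSE)
  stopifnot(all(vapply(fits, inherits, logical(1), "fit_result")))
  n <- vapply(fits, function(f) f$n_events + f$n_censored, numeric(1))
  if (length(unique(n)) != 1L) {
    stop("fits were computed on different datasets (sample sizes ",
         paste(unique(n), collapse = ", "), "); AIC is not comparable",
         call. = FALSE)
  }
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  k <- vapply(fits, function(f) f$n_params, numeric(1))
  fam <- vapply(fits, function(f) match(f$curve$family, SURV_FAMILIES),
                numeric(1))
  fits[[order(aic, k, fam)[1]]]
}
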