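#' Round half away from zero
#'
#' Commercial ("half-up") rounding used when printing monetary amounts, so
#' that e.g. 0.5 euro rounds to 1 rather than to 0 as under banker's
#' rounding.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(2.5)   # 3
#' round_half_up(-2.5)  # -3
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

split_path <- function(path) strsplit(path, ".", fixed = TRUE)[[1]]

path_key <- function(k) {
  if (grepl("^[0-9]+$", k)) as.integer(k) else k
}

#' Read a value from a model configuration by dotted path
#'
#' Paths address nested configuration fields, e.g.
#' `"utilities.u_pre"` or
#' `"arms.bev_pacl.pre_progression_cycle_costs.drug_acquisition"`.
#' Purely numeric segments index list positions (1-based).
#'
#' @param config A [model_config] (or any nested list).
#' @param path Dotted character path.
#' @return The value at `path`.
#' @export
config_get <- function(config, path) {
  keys <- split_path(path)
  node <- config
  for (i in seq_along(keys)) {
    k <- path_key(keys[i])
    if (is.numeric(k)) {
      if (k < 1 || k > length(node)) {
        stop("config path '", path, "' does not resolve: index ", k,
             " out of range at '", keys[i], "'", call. = FALSE)
      }
    } else if (!is.list(node) || !(k %in% names(node))) {
      stop("config path '", path, "' does not resolve: no element '",
           k, "'", call. = FALSE)
    }
    node <- node[[k]]
  }
  node
}

#' Set a value in a model configuration by dotted path
#'
#' @inheritParams config_get
#' @param value Replacement value.
#' @return The modified configuration; the path must already resolve
#'   (sensitivity analyses may only vary existing parameters).
#' @export
config_set <- function(config, path, value) {
  config_get(config, path) # errors if the path does not resolve
  keys <- split_path(path)
  set_rec <- function(node, keys) {
    k <- path_key(keys[1])
    if (length(keys) == 1L) {
      node[[k]] <- value
    } else {
      node[[k]] <- set_rec(node[[k]], keys[-1])
    }
    node
  }
  set_rec(config, keys)
}

stop_if_not_number <- function(x, what, lower = -Inf, upper = Inf,
                               open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single number (got ",
         paste(deparse(x), collapse = ""), ")", call. = FALSE)
  }
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop(what, " = ", x, " outside the valid range ",
         if (open_lower) "(" else "[", lower, ", ", upper,
         if (open_upper) ")" else "]", call. = FALSE)
  }
  invisible(x)
}
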