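# Dimensionless scaling of raw indicator values.

#' Threshold (min-max) standardization across alternatives
#'
#' Scales the raw values of one leaf indicator across alternatives to
#' \[0, 1\] by `y = (x - min(x)) / (max(x) - min(x))`. For a reverse
#' indicator (smaller is better) the raw data are negated first, so the
#' cheapest/least-damaging alternative maps to 1 and the worst to 0. When all
#' values are identical the range is degenerate; every alternative is then
#' assigned 0.5 (the indifference point of the scale) with a warning.
#'
#' @param x Numeric vector of raw values, one per alternative (length >= 2).
#' @param direction `"positive"` (bigger is better) or `"reverse"` (smaller
#'   is better).
#' @return Numeric vector of standardized values in \[0, 1\].
#' @examples
#' threshold_standardize(c(2, 4, 10))                 # 0, 0.25, 1
#' threshold_standardize(c(148.44, 104.65), "reverse") # 0, 1
#' @export
threshold_standardize <- function(x, direction = c("positive", "reverse")) {
  direction <- match.arg(direction)
  x <- as.numeric(x)
  if (length(x) < 2L) {
    fahp_error("threshold standardization needs at least two alternatives",
               "fahp_validation")
  }
  if (anyNA(x)) fahp_error("raw values must not be missing", "fahp_missing_value")
  if (direction == "reverse") x <- -x
  rng <- range(x)
  if (diff(rng) == 0) {
    warning("degenerate range (all values identical): returning 0.5 for every alternative")
    return(rep(0.5, length(x)))
  }
  (x - rng[1L]) / diff(rng)
}

#' Fractional standardization of percentage data
#'
#' Converts data already expressed as a percentage to a decimal fraction.
#'
#' @param x Numeric vector of percentages in \[0, 100\].
#' @return `x / 100`.
#' @examples
#' fraction_standardize(29.5)  # 0.295
#' @export
fraction_standardize <- function(x) {
  x <- as.numeric(x)
  if (anyNA(x) || any(x < 0 | x > 100)) {
    fahp_error("percentages must lie in [0, 100]", "fahp_validation")
  }
  x / 100
}

#' Standardize a raw indicator value table against a hierarchy
#'
#' Applies per-leaf standardization driven by each leaf's direction flag:
#' `positive` and `reverse` leaves go through [threshold_standardize()]
#' across the alternatives; `graded` leaves are qualitative five-grade expert
#' scores already on \[0, 1\] and are passed through unchanged (values
#' outside \[0, 1\] on a graded leaf are an error).
#'
#' @param values Data frame with columns `leaf`, `alternative`, `value`
#'   (raw), one row per leaf x alternative.
#' @param hierarchy An `"fahp_hierarchy"` supplying leaf directions and the
#'   alternative set.
#' @return The input data frame with an added `standardized` column.
#' @export
standardize_values <- function(values, hierarchy) {
  stopifnot(inherits(hierarchy, "fahp_hierarchy"))
  values <- check_value_table(values, hierarchy)
  values$standardized <- NA_real_
  for (leaf in hierarchy$leaves) {
    idx <- which(values$leaf == leaf)
    idx <- idx[match(hierarchy$alternatives, values$alternative[idx])]
    dir <- hierarchy$nodes[[leaf]]$direction
    if (dir == "graded") {
      v <- values$value[idx]
      if (any(v < 0 | v > 1)) {
        fahp_error(sprintf("graded leaf '%s' has values outside [0, 1]", leaf),
                   "fahp_validation")
      }
      values$standardized[idx] <- v
    } else {
      values$standardized[idx] <- threshold_standardize(values$value[idx], dir)
    }
  }
  values
}

# one row per (leaf, alternative), no gaps, no strays
check_value_table <- function(values, hierarchy) {
  req <- c("leaf", "alternative", "value")
  if (!is.data.frame(values) || !all(req %in% names(values))) {
    fahp_error("`values` must have columns leaf, alternative, value", "fahp_validation")
  }
  values$leaf <- as.character(values$leaf)
  values$alternative <- as.character(values$alternative)
  stray <- setdiff(values$leaf, hierarchy$leaves)
  if (length(stray)) {
    fahp_error(sprintf("values given for non-leaf id(s): %s",
                       paste(stray, collapse = ", ")), "fahp_unknown_node")
  }
  want <- expand.grid(leaf = hierarchy$leaves, alternative = hierarchy$alternatives,
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$leaf, d$alternative, sep = "\r")
  miss <- setdiff(key(want), key(values))
  if (length(miss)) {
    fahp_error(sprintf("missing value(s) for (leaf, alternative): %s",
                       paste(gsub("\r", "/", utils::head(miss, 5L)), collapse = ", ")),
               "fahp_missing_value")
  }
  if (anyDuplicated(key(values))) {
    fahp_error("duplicated (leaf, alternative) rows in `values`", "fahp_duplicate_id")
  }
  values
}
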