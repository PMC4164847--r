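# Hierarchical weight synthesis and the comprehensive evaluation score.

#' Composite leaf weights by the path-product rule
#'
#' The composite (synthesized) weight of a leaf is the product of the local
#' weights along the path from the root to that leaf. Because each sibling
#' group's local weights sum to 1, the composite weights of all leaves sum to
#' 1 as well.
#'
#' @param hierarchy An `"fahp_hierarchy"` whose internal nodes all have
#'   weighted children (from the config file or from [fahp()] /
#'   [set_local_weights()]).
#' @return Named numeric vector: leaf id -> composite weight.
#' @export
composite_weights <- function(hierarchy) {
  stopifnot(inherits(hierarchy, "fahp_hierarchy"))
  lam <- stats::setNames(numeric(length(hierarchy$leaves)), hierarchy$leaves)
  for (leaf in hierarchy$leaves) {
    w <- 1
    id <- leaf
    while (id != hierarchy$root) {
      lw <- hierarchy$nodes[[id]]$local_weight
      if (is.na(lw)) {
        fahp_error(sprintf("node '%s' has no local weight; weight its parent's children first", id),
                   "fahp_missing_weight")
      }
      w <- w * lw
      id <- hierarchy$nodes[[id]]$parent
    }
    lam[[leaf]] <- w
  }
  if (abs(sum(lam) - 1) > 1e-6) {
    fahp_error(sprintf("composite weights sum to %.8f, not 1", sum(lam)), "fahp_validation")
  }
  lam
}

#' Fit a fuzzy-AHP comprehensive evaluation
#'
#' The package's central fitting function. Given an indicator hierarchy,
#' per-leaf indicator values for each alternative, and (optionally) expert
#' panels for the internal nodes, it
#' \enumerate{
#'   \item derives each node's local child weights from its expert panel via
#'     [node_weights()] (nodes without a panel keep the weights already
#'     stored in the hierarchy),
#'   \item synthesizes composite leaf weights by the path-product rule,
#'   \item standardizes raw values (optional; see [standardize_values()]),
#'   \item scores every alternative by the linear-weighted comprehensive
#'     index `P = sum_i x_i * lambda_i + c`, where `x_i` is the standardized
#'     value of leaf i, `lambda_i` its composite weight and `c` a correction
#'     for interference factors not captured by the hierarchy (0 by default,
#'     i.e. positive and negative interference assumed to cancel).
#' }
#'
#' @param hierarchy An `"fahp_hierarchy"`.
#' @param values Data frame with columns `leaf`, `alternative`, `value`. With
#'   `standardize = FALSE` (default) `value` must already be a standardized
#'   fraction in \[0, 1\]; with `standardize = TRUE` raw values are
#'   standardized per leaf direction first.
#' @param panels Optional named list of [expert_panel()] objects and/or
#'   aggregated fuzzy judgment matrices, keyed by internal node id.
#' @param method Weighting method for panel nodes: `"iterative"` (default),
#'   `"normalizing"` or `"sqrt"`; see [node_weights()].
#' @param correction Correction value `c` added to every score (default 0).
#' @param standardize Logical; standardize raw `value`s first.
#' @param tol,max_iter Power-iteration controls for `method = "iterative"`.
#' @return An object of class `"fahp"` with components `hierarchy` (weights
#'   filled in), `lambda` (composite leaf weights), `values` (long table with
#'   `standardized` and `integrated = standardized * lambda` columns),
#'   `scores` (named vector of P per alternative), `correction`, `method`
#'   and `call`. Methods: [print.fahp()], [summary.fahp()], `coef()`
#'   (composite weights), [predict.fahp()], `plot()` and
#'   [compare_alternatives()].
#' @examples
#' h <- build_hierarchy(
#'   list(A  = list(children = c("B1", "B2")),
#'        B1 = list(direction = "positive", weight = 0.6),
#'        B2 = list(direction = "reverse",  weight = 0.4)),
#'   alternatives = c("p", "q"))
#' v <- data.frame(leaf = c("B1", "B1", "B2", "B2"),
#'                 alternative = c("p", "q", "p", "q"),
#'                 value = c(10, 30, 5, 2))
#' fit <- fahp(h, v, standardize = TRUE)
#' fit$scores
#' @export
fahp <- function(hierarchy, values, panels = NULL,
                 method = c("iterative", "normalizing", "sqrt"),
                 correction = 0, standardize = FALSE,
                 tol = 1e-4, max_iter = 100L) {
  stopifnot(inherits(hierarchy, "fahp_hierarchy"))
  method <- match.arg(method)

  if (!is.null(panels)) {
    if (is.null(names(panels))) {
      nm <- vapply(panels, function(p)
        if (inherits(p, "fahp_panel")) p$node_id else NA_character_, character(1))
      if (anyNA(nm)) fahp_error("`panels` must be named by node id", "fahp_validation")
      names(panels) <- nm
    }
    for (id in names(panels)) {
      w <- node_weights(panels[[id]], method = method, tol = tol, max_iter = max_iter)
      hierarchy <- set_local_weights(hierarchy, id, as.numeric(w))
    }
  }

  lam <- composite_weights(hierarchy)

  if (standardize) {
    values <- standardize_values(values, hierarchy)
  } else {
    values <- check_value_table(values, hierarchy)
    if (any(values$value < 0 | values$value > 1)) {
      fahp_error("standardized values must lie in [0, 1] (or pass standardize = TRUE)",
                 "fahp_validation")
    }
    values$standardized <- values$value
  }
  values$integrated <- values$standardized * lam[values$leaf]

  scores <- vapply(hierarchy$alternatives, function(a)
    sum(values$integrated[values$alternative == a]) + correction, numeric(1))

  structure(list(hierarchy = hierarchy, lambda = lam, values = values,
                 scores = scores, correction = correction, method = method,
                 call = match.call()),
            class = "fahp")
}

#' @export
print.fahp <- function(x, digits = 4, ...) {
  cat("Fuzzy-AHP comprehensive evaluation (", x$method, " weights)\n", sep = "")
  cat(length(x$lambda), "leaf indicators,",
      length(x$hierarchy$alternatives), "alternatives; correction c =",
      x$correction, "\n\nComprehensive scores P:\n")
  print(round(sort(x$scores, decreasing = TRUE), digits))
  invisible(x)
}

#' @export
coef.fahp <- function(object, ...) object$lambda

#' Summarize a fitted evaluation as a per-leaf table
#'
#' Produces the full evaluation table: one row per leaf with its label,
#' composite weight, and per-alternative standardized and integrated
#' (`standardized * weight`) values -- the layout in which hierarchical
#' evaluation results are conventionally reported. Printed values are
#' rounded to 4 decimals; the underlying table is not.
#'
#' @param object An `"fahp"` fit.
#' @param ... Unused.
#' @return A `"summary.fahp"` object: list with `table` (data frame),
#'   `scores`, `correction` and `method`.
#' @export
summary.fahp <- function(object, ...) {
  h <- object$hierarchy
  tab <- data.frame(leaf = names(object$lambda),
                    label = vapply(h$nodes[names(object$lambda)], `[[`, character(1), "label"),
                    direction = vapply(h$nodes[names(object$lambda)], `[[`, character(1), "direction"),
                    weight = as.numeric(object$lambda),
                    row.names = NULL, stringsAsFactors = FALSE)
  for (a in h$alternatives) {
    va <- object$values[object$values$alternative == a, ]
    ord <- match(tab$leaf, va$leaf)
    tab[[paste0("std.", a)]] <- va$standardized[ord]
    tab[[paste0("int.", a)]] <- va$integrated[ord]
  }
  structure(list(table = tab, scores = object$scores,
                 correction = object$correction, method = object$method),
            class = "summary.fahp")
}

#' @export
print.summary.fahp <- function(x, digits = 4, ...) {
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits)
  print(tab, row.names = FALSE)
  cat("\nComprehensive scores (c = ", x$correction, "):\n", sep = "")
  print(round(x$scores, digits))
  invisible(x)
}

#' Score new alternatives with fitted weights
#'
#' Applies the composite weights of a fitted evaluation to a new table of
#' leaf values, returning the comprehensive score of each alternative in
#' `newdata` without re-deriving any weights.
#'
#' @param object An `"fahp"` fit.
#' @param newdata Data frame with columns `leaf`, `alternative`, `value`
#'   (standardized fractions, or raw with `standardize = TRUE`). The
#'   alternatives may differ from those used in the fit.
#' @param standardize Logical; min-max standardize `newdata` across its own
#'   alternatives first.
#' @param ... Unused.
#' @return Named numeric vector of scores P.
#' @export
predict.fahp <- function(object, newdata, standardize = FALSE, ...) {
  h <- object$hierarchy
  h$alternatives <- unique(as.character(newdata$alternative))
  refit <- fahp(h, newdata, correction = object$correction,
                standardize = standardize)
  refit$scores
}

#' @export
plot.fahp <- function(x, ...) {
  s <- sort(x$scores, decreasing = TRUE)
  graphics::barplot(s, ylab = "comprehensive score P", ylim = c(0, max(1, s)),
                    main = "Fuzzy-AHP evaluation", ...)
  invisible(x)
}

#' Rank alternatives by comprehensive score
#'
#' @param x An `"fahp"` fit, or a named numeric vector of scores.
#' @return Data frame sorted by decreasing P with columns `alternative`, `P`,
#'   `rank` and `delta_next` (gap to the next-ranked alternative, NA for the
#'   last). Ties keep input order.
#' @examples
#' compare_alternatives(c(road = 0.4473, cableway = 0.6727))
#' @export
compare_alternatives <- function(x) {
  s <- if (inherits(x, "fahp")) x$scores else x
  if (length(s) < 2L) fahp_error("need at least two alternatives to compare", "fahp_validation")
  ord <- order(-as.numeric(s))
  out <- data.frame(alternative = names(s)[ord], P = as.numeric(s)[ord],
                    rank = seq_along(s), stringsAsFactors = FALSE)
  out$delta_next <- c(-diff(out$P), NA_real_)
  out
}

#' Write the evaluation table to a delimited file
#'
#' Emits the [summary.fahp()] table as tab-separated text with numeric
#' columns rounded to 4 decimals, followed by nothing else -- a
#' machine-readable version of the standard evaluation report.
#'
#' @param object An `"fahp"` fit.
#' @param file Path, or `""` for stdout.
#' @return The (unrounded) table, invisibly.
#' @export
fahp_report <- function(object, file = "") {
  tab <- summary(object)$table
  out <- tab
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round, 4)
  utils::write.table(out, file = file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
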