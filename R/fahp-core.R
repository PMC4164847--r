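# Improved-FAHP calculus on three-scale complementary judgment matrices:
#   expert panel -> F (fuzzy judgment) -> R (fuzzy consistent)
#     -> priority vector (normalizing / square-root)
#     -> E (positive reciprocal) -> power-iterated ranking vector.

#' Expert panel of pairwise three-scale scores
#'
#' Bundles the raw pairwise comparison scores that a panel of experts assigned
#' to the children of one hierarchy node. Each expert scores every unordered
#' pair (i, j) of children on the three-scale division: 0 (i less important
#' than j), 0.5 (equally important), 1 (i more important than j).
#'
#' @param node_id Id of the parent node whose children are compared.
#' @param children Character vector of the children being compared, in the
#'   order that defines the rows/columns of the aggregated matrix.
#' @param scores Data frame with columns `i`, `j` (child ids), `expert`
#'   (expert id) and `score` (0, 0.5 or 1, meaning "i vs j"). Rows given with
#'   the pair in reversed child order are flipped (score -> 1 - score), so
#'   either orientation may be recorded. Every pair must be scored by the
#'   same number of experts k >= 1.
#' @return An object of class `"fahp_panel"`.
#' @examples
#' p <- expert_panel("A", c("B1", "B2"),
#'                   data.frame(i = "B1", j = "B2", expert = 1:3,
#'                              score = c(1, 1, 0.5)))
#' aggregate_scores(p)
#' @export
expert_panel <- function(node_id, children, scores) {
  children <- as.character(children)
  n <- length(children)
  if (n < 2L) fahp_error("a panel needs at least two children", "fahp_validation")
  if (anyDuplicated(children)) fahp_error("duplicated child ids", "fahp_duplicate_id")
  req <- c("i", "j", "expert", "score")
  if (!is.data.frame(scores) || !all(req %in% names(scores))) {
    fahp_error("`scores` must have columns i, j, expert, score", "fahp_validation")
  }
  scores$i <- as.character(scores$i); scores$j <- as.character(scores$j)
  if (!all(c(scores$i, scores$j) %in% children)) {
    fahp_error("scores refer to ids that are not children of the node", "fahp_unknown_node")
  }
  if (any(scores$i == scores$j)) fahp_error("self-comparisons are not allowed", "fahp_validation")
  if (!all(scores$score %in% c(0, 0.5, 1))) {
    fahp_error("every score must be 0, 0.5 or 1 (three-scale division)", "fahp_validation")
  }
  # canonical orientation: i before j in child order
  pi <- match(scores$i, children); pj <- match(scores$j, children)
  flip <- pi > pj
  if (any(flip)) {
    tmp <- scores$i[flip]; scores$i[flip] <- scores$j[flip]; scores$j[flip] <- tmp
    scores$score[flip] <- 1 - scores$score[flip]
  }
  pairs <- paste(scores$i, scores$j, sep = "\r")
  want <- outer(seq_len(n), seq_len(n), function(a, b) a < b)
  all_pairs <- paste(children[row(want)[want]], children[col(want)[want]], sep = "\r")
  k <- table(factor(pairs, levels = all_pairs))
  if (any(k == 0L)) {
    miss <- all_pairs[k == 0L][1L]
    fahp_error(sprintf("no scores for pair (%s)", gsub("\r", ", ", miss)),
               "fahp_missing_value")
  }
  if (length(unique(as.integer(k))) != 1L) {
    fahp_error("all pairs must be scored by the same number of experts", "fahp_validation")
  }
  structure(list(node_id = node_id, children = children,
                 scores = scores[order(pi, pj), req, drop = FALSE],
                 n_experts = as.integer(k[[1L]])),
            class = "fahp_panel")
}

#' @export
print.fahp_panel <- function(x, ...) {
  cat("Expert panel for node '", x$node_id, "': ", length(x$children),
      " children, ", x$n_experts, " expert(s), ",
      nrow(x$scores), " scores\n", sep = "")
  invisible(x)
}

#' Aggregate expert scores into a fuzzy judgment matrix
#'
#' For each pair of children the score chosen by the most experts (the
#' plurality over \{0, 0.5, 1\}) becomes the matrix entry `f[i, j]`;
#' `f[j, i] = 1 - f[i, j]` and the diagonal is 0.5, so the result is a
#' complementary matrix. When no single score has a strict plurality the
#' entry falls back to 0.5 (equal importance) -- the only tie-break that is
#' symmetric in the two children and independent of score order.
#'
#' @param panel An [expert_panel()].
#' @return An n x n complementary fuzzy judgment matrix with entries in
#'   \{0, 0.5, 1\}, dimnames set to the child ids.
#' @examples
#' # seven experts, plurality at 0
#' p <- expert_panel("A", c("x", "y"),
#'                   data.frame(i = "x", j = "y", expert = 1:7,
#'                              score = c(0, 0, 0.5, 1, 0.5, 0, 1)))
#' aggregate_scores(p)["x", "y"]  # 0
#' @export
aggregate_scores <- function(panel) {
  stopifnot(inherits(panel, "fahp_panel"))
  ch <- panel$children
  n <- length(ch)
  f <- matrix(0.5, n, n, dimnames = list(ch, ch))
  sc <- panel$scores
  for (p in split(sc, paste(sc$i, sc$j, sep = "\r"))) {
    if (nrow(p) == 0L) fahp_error("empty score list for a pair", "fahp_missing_value")
    cnt <- vapply(c(0, 0.5, 1), function(s) sum(p$score == s), numeric(1))
    top <- which(cnt == max(cnt))
    val <- if (length(top) == 1L) c(0, 0.5, 1)[top] else 0.5
    f[p$i[1L], p$j[1L]] <- val
    f[p$j[1L], p$i[1L]] <- 1 - val
  }
  f
}

check_judgment <- function(f) {
  if (!is.matrix(f) || nrow(f) != ncol(f) || nrow(f) < 2L) {
    fahp_error("a fuzzy judgment matrix must be square, n >= 2", "fahp_validation")
  }
  if (!all(f %in% c(0, 0.5, 1))) {
    fahp_error("fuzzy judgment entries must be 0, 0.5 or 1", "fahp_validation")
  }
  if (any(diag(f) != 0.5)) fahp_error("diagonal of F must be 0.5", "fahp_validation")
  if (any(abs(f + t(f) - 1) > 0)) {
    fahp_error("F is not complementary: f[i,j] + f[j,i] must equal 1", "fahp_validation")
  }
  invisible(f)
}

check_complementary <- function(r, tol = 1e-9) {
  if (!is.matrix(r) || nrow(r) != ncol(r)) {
    fahp_error("expected a square matrix", "fahp_validation")
  }
  if (any(r < -tol) || any(r > 1 + tol) || any(abs(r + t(r) - 1) > tol)) {
    fahp_error("matrix is not fuzzy complementary (entries in [0,1], r + t(r) = 1)",
               "fahp_validation")
  }
  invisible(r)
}

#' Fuzzy consistent matrix from a fuzzy judgment matrix
#'
#' Applies the row-sum conversion `r[i,j] = (r_i - r_j) / (2n) + 0.5`, where
#' `r_i` is the i-th row sum of `F`. The result is additively consistent by
#' construction (`r[i,j] = r[i,k] - r[j,k] + 0.5` for every triple), so no
#' separate consistency check is needed downstream.
#'
#' @param f Complementary fuzzy judgment matrix with entries in \{0, 0.5, 1\}.
#' @return The n x n fuzzy consistent matrix, with the row sums of `F`
#'   attached as attribute `"row_sums"`.
#' @examples
#' f <- matrix(c(0.5, 1, 1,
#'               0,   0.5, 1,
#'               0,   0,   0.5), 3, byrow = TRUE)
#' round(to_consistent(f), 3)
#' @export
to_consistent <- function(f) {
  check_judgment(f)
  n <- nrow(f)
  rs <- rowSums(f)
  r <- outer(rs, rs, "-") / (2 * n) + 0.5
  dimnames(r) <- dimnames(f)
  attr(r, "row_sums") <- rs
  r
}

new_weights <- function(w, method, lambda_max = NA_real_, iterations = NA_integer_) {
  structure(as.numeric(w) / sum(w),
            names = names(w),
            method = method, lambda_max = lambda_max,
            iterations = iterations, class = "fahp_weights")
}

#' @export
print.fahp_weights <- function(x, digits = 4, ...) {
  cat("Priority vector (", attr(x, "method"), " method)\n", sep = "")
  print(round(stats::setNames(as.numeric(x), names(x)), digits))
  if (!is.na(attr(x, "lambda_max"))) {
    cat("lambda_max =", format(attr(x, "lambda_max"), digits = digits + 1),
        "in", attr(x, "iterations"), "iteration(s)\n")
  }
  invisible(x)
}

#' Priority vectors from a fuzzy consistent matrix
#'
#' Two closed-form ranking vectors over a node's children:
#' `weights_normalizing()` uses row sums, `w_i = sum_j r[i,j] / sum_ij r[i,j]`;
#' `weights_sqrt()` uses the geometric (n-th root) mean of each row,
#' normalized to sum 1. Both preserve the importance ordering induced by the
#' row sums of the originating judgment matrix. `weights_sqrt()` is undefined
#' when any entry is 0 (a unanimous extreme judgment at small n) and raises a
#' degenerate-matrix error in that case.
#'
#' @param r Fuzzy consistent (complementary) matrix.
#' @return An `"fahp_weights"` vector summing to 1.
#' @examples
#' r <- to_consistent(matrix(c(0.5, 1, 1, 0, 0.5, 1, 0, 0, 0.5), 3, byrow = TRUE))
#' round(weights_normalizing(r), 4)  # 0.4444 0.3333 0.2222
#' round(weights_sqrt(r), 4)         # 0.4543 0.3348 0.2109
#' @export
weights_normalizing <- function(r) {
  check_complementary(r)
  new_weights(stats::setNames(rowSums(r), rownames(r)), "normalizing")
}

#' @rdname weights_normalizing
#' @export
weights_sqrt <- function(r) {
  check_complementary(r)
  if (any(r == 0)) {
    fahp_error("degenerate matrix: a zero entry makes the geometric mean undefined",
               "fahp_degenerate")
  }
  n <- nrow(r)
  g <- apply(r, 1L, function(row) exp(mean(log(row))))
  new_weights(stats::setNames(g, rownames(r)), "sqrt")
}

#' Positive reciprocal matrix from a fuzzy consistent matrix
#'
#' Converts a complementary matrix to the multiplicative scale by
#' `e[i,j] = r[i,j] / r[j,i]`, yielding a positive reciprocal matrix
#' (`e[i,j] * e[j,i] = 1`, unit diagonal) whose principal eigenvector refines
#' the priorities. Entries of 0 or 1 in `r` (possible only for extreme
#' judgments at small n) make the ratio degenerate and raise an error naming
#' the offending pair.
#'
#' @param r Fuzzy consistent (complementary) matrix with off-diagonal entries
#'   strictly inside (0, 1).
#' @return The n x n positive reciprocal matrix.
#' @examples
#' r <- to_consistent(matrix(c(0.5, 1, 1, 0, 0.5, 1, 0, 0, 0.5), 3, byrow = TRUE))
#' to_reciprocal(r)
#' @export
to_reciprocal <- function(r) {
  check_complementary(r)
  off <- r[row(r) != col(r)]
  if (any(off <= 0 | off >= 1)) {
    bad <- which(r <= 0 | r >= 1, arr.ind = TRUE)
    bad <- bad[bad[, 1L] != bad[, 2L], , drop = FALSE][1L, ]
    fahp_error(sprintf("cannot form reciprocal matrix: r[%d,%d] = %g is 0 or 1",
                       bad[1L], bad[2L], r[bad[1L], bad[2L]]), "fahp_degenerate")
  }
  e <- r / t(r)
  attr(e, "row_sums") <- NULL
  e
}

#' Power iteration for the dominant eigenvector of a reciprocal matrix
#'
#' Iterates `V_(k+1) = E %*% Y_k`, `Y_k = V_k / ||V_k||_inf`, starting from a
#' strictly positive seed, until the infinity norm of the change in the
#' normalized iterate falls below `tol`. The dominant-eigenvalue estimate
#' `lambda_max` is reported as the infinity norm of the final unnormalized
#' iterate; the returned ranking vector is the final iterate normalized to
#' sum 1. Seeding with the [weights_normalizing()] vector of the underlying
#' consistent matrix typically converges in a handful of iterations.
#'
#' @param e Positive reciprocal matrix.
#' @param seed Strictly positive start vector (default: uniform).
#' @param tol Convergence tolerance on successive infinity-normalized
#'   iterates (default 1e-4).
#' @param max_iter Iteration cap; exceeding it raises a convergence error
#'   that reports the last residual.
#' @return An `"fahp_weights"` vector with attributes `lambda_max` and
#'   `iterations`. For an n x n positive reciprocal matrix
#'   `lambda_max >= n` (Perron bound).
#' @examples
#' r <- to_consistent(matrix(c(0.5, 1, 1, 0, 0.5, 1, 0, 0, 0.5), 3, byrow = TRUE))
#' power_iterate(to_reciprocal(r), seed = weights_normalizing(r))
#' @export
power_iterate <- function(e, seed = NULL, tol = 1e-4, max_iter = 100L) {
  if (!is.matrix(e) || nrow(e) != ncol(e) || any(e <= 0) ||
      any(abs(e * t(e) - 1) > 1e-9)) {
    fahp_error("`e` must be a positive reciprocal matrix (e * t(e) = 1)",
               "fahp_validation")
  }
  n <- nrow(e)
  if (is.null(seed)) seed <- rep(1 / n, n)
  v <- as.numeric(seed)
  if (length(v) != n || any(v <= 0)) {
    fahp_error("seed must be strictly positive, length n", "fahp_validation")
  }
  if (max_iter < 1L) fahp_error("`max_iter` must be at least 1", "fahp_validation")
  y_prev <- v / max(v)
  res <- Inf
  for (k in seq_len(max_iter)) {
    v <- as.numeric(e %*% y_prev)
    y <- v / max(v)
    res <- max(abs(y - y_prev))
    if (res < tol) {
      return(new_weights(stats::setNames(v, rownames(e)), "iterative",
                         lambda_max = max(v), iterations = as.integer(k)))
    }
    y_prev <- y
  }
  fahp_error(sprintf("power iteration did not converge in %d iterations (last residual %.3g)",
                     max_iter, res), "fahp_convergence")
}

#' Per-node weight pipeline
#'
#' Convenience composition of the whole calculus for one hierarchy node:
#' aggregate the expert panel (if needed), transform to the fuzzy consistent
#' matrix, then either take a closed-form vector (`"normalizing"`, `"sqrt"`)
#' or refine by the reciprocal-matrix power iteration seeded with the
#' normalizing vector (`"iterative"`, the default and the method whose
#' results the bundled case study reports).
#'
#' @param x An [expert_panel()] or an already-aggregated complementary fuzzy
#'   judgment matrix.
#' @param method `"iterative"`, `"normalizing"` or `"sqrt"`.
#' @param tol,max_iter Passed to [power_iterate()] for the iterative method.
#' @return An `"fahp_weights"` vector over the node's children.
#' @examples
#' f <- matrix(c(0.5, 1, 1, 0, 0.5, 1, 0, 0, 0.5), 3, byrow = TRUE)
#' round(node_weights(f), 4)  # 0.5954 0.2763 0.1283
#' @export
node_weights <- function(x, method = c("iterative", "normalizing", "sqrt"),
                         tol = 1e-4, max_iter = 100L) {
  method <- match.arg(method)
  f <- if (inherits(x, "fahp_panel")) aggregate_scores(x) else x
  r <- to_consistent(f)
  switch(method,
    normalizing = weights_normalizing(r),
    sqrt = weights_sqrt(r),
    iterative = power_iterate(to_reciprocal(r), seed = weights_normalizing(r),
                              tol = tol, max_iter = max_iter))
}
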