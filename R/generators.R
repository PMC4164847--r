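# Synthetic fixtures: reproducible expert panels, hierarchies and value
# tables with the structure the calculus assumes.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Generate a random expert panel
#'
#' Draws `n_experts` independent three-scale scores for every unordered pair
#' of children, i.i.d. from \{0, 0.5, 1\} with probabilities `prob`. The
#' default is uniform; skewing `prob` towards an extreme emulates a
#' strong-consensus panel (and `prob = c(1, 0, 0)` produces the unanimous
#' extreme judgments that make the reciprocal conversion degenerate, useful
#' for exercising error paths). With the same `seed` and configuration the
#' output is identical.
#'
#' @param children Character vector (length >= 2) of compared child ids.
#' @param n_experts Number of experts k >= 1 (default 7).
#' @param prob Probabilities of scores 0, 0.5, 1 (default uniform).
#' @param node_id Id of the parent node (cosmetic).
#' @param seed Optional integer seed; the global RNG state is restored
#'   afterwards.
#' @return An [expert_panel()].
#' @export
generate_panel <- function(children, n_experts = 7L, prob = c(1, 1, 1) / 3,
                           node_id = "node", seed = NULL) {
  stopifnot(length(children) >= 2L, n_experts >= 1L, length(prob) == 3L)
  with_seed(seed, {
    n <- length(children)
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    scores <- do.call(rbind, lapply(seq_len(nrow(idx)), function(p) {
      data.frame(i = children[idx[p, 1L]], j = children[idx[p, 2L]],
                 expert = seq_len(n_experts),
                 score = sample(c(0, 0.5, 1), n_experts, replace = TRUE, prob = prob),
                 stringsAsFactors = FALSE)
    }))
    expert_panel(node_id, children, scores)
  })
}

#' Generate panels for every internal node of a hierarchy
#'
#' @param hierarchy An `"fahp_hierarchy"`.
#' @param n_experts,prob As in [generate_panel()].
#' @param seed Optional integer seed covering the whole panel set.
#' @return Named list of panels keyed by internal node id (nodes with at
#'   least two children).
#' @export
generate_panels <- function(hierarchy, n_experts = 7L, prob = c(1, 1, 1) / 3,
                            seed = NULL) {
  stopifnot(inherits(hierarchy, "fahp_hierarchy"))
  internal <- Filter(function(n) length(n$children) >= 2L, hierarchy$nodes)
  with_seed(seed, {
    out <- lapply(internal, function(n)
      generate_panel(n$children, n_experts = n_experts, prob = prob, node_id = n$id))
    stats::setNames(out, vapply(internal, `[[`, character(1), "id"))
  })
}

#' Generate a random layered hierarchy
#'
#' Builds a balanced-depth tree: every internal node at a given level draws
#' its child count uniformly from `n_children`, and all leaves sit at depth
#' `depth`. Leaf directions are drawn with probabilities `p_reverse` /
#' `p_graded` (positive otherwise), mirroring evaluation systems in which
#' most indicators are benefit-type with a few cost-type and qualitative
#' ones.
#'
#' @param depth Number of levels below the root (default 3, as in a
#'   target / criterion / subcriterion / indicator layout).
#' @param n_children Integer range `c(min, max)` of children per internal
#'   node (default 3 to 9, nine being the conventional ceiling for a
#'   pairwise-comparable sibling group).
#' @param n_alternatives Number of alternatives (default 2).
#' @param p_reverse,p_graded Probabilities of a leaf being reverse / graded.
#' @param seed Optional integer seed.
#' @return An `"fahp_hierarchy"` (without local weights).
#' @export
random_hierarchy <- function(depth = 3L, n_children = c(3L, 9L),
                             n_alternatives = 2L, p_reverse = 0.1,
                             p_graded = 0.05, seed = NULL) {
  stopifnot(depth >= 1L, n_children[1L] >= 2L, n_alternatives >= 1L)
  with_seed(seed, {
    nodes <- list(A = list(label = "target", children = character(0)))
    frontier <- "A"
    counter <- 0L
    for (lev in seq_len(depth)) {
      nxt <- character(0)
      for (id in frontier) {
        k <- sample(seq(n_children[1L], n_children[2L]), 1L)
        kids <- paste0("N", counter + seq_len(k))
        counter <- counter + k
        nodes[[id]]$children <- kids
        for (kid in kids) nodes[[kid]] <- list(label = kid, children = character(0))
        nxt <- c(nxt, kids)
      }
      frontier <- nxt
    }
    for (id in frontier) {
      nodes[[id]]$children <- NULL
      u <- stats::runif(1)
      nodes[[id]]$direction <-
        if (u < p_reverse) "reverse" else if (u < p_reverse + p_graded) "graded" else "positive"
    }
    build_hierarchy(nodes, paste0("alt", seq_len(n_alternatives)))
  })
}

#' Generate a random raw indicator value table
#'
#' Draws raw values for every (leaf, alternative) cell: uniform on `range`
#' for positive/reverse leaves and uniform on \[0, 1\] for graded leaves
#' (which are expert scores by definition).
#'
#' @param hierarchy An `"fahp_hierarchy"`.
#' @param range Range of raw values for threshold-standardized leaves.
#' @param seed Optional integer seed.
#' @return Data frame with columns `leaf`, `alternative`, `value`, suitable
#'   for `fahp(..., standardize = TRUE)`.
#' @export
random_values <- function(hierarchy, range = c(0, 100), seed = NULL) {
  stopifnot(inherits(hierarchy, "fahp_hierarchy"))
  with_seed(seed, {
    grid <- expand.grid(leaf = hierarchy$leaves,
                        alternative = hierarchy$alternatives,
                        stringsAsFactors = FALSE)
    dirs <- vapply(hierarchy$nodes[grid$leaf], `[[`, character(1), "direction")
    grid$value <- ifelse(dirs == "graded", stats::runif(nrow(grid)),
                         stats::runif(nrow(grid), range[1L], range[2L]))
    grid
  })
}
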