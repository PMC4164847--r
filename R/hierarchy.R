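# Indicator hierarchy: a rooted tree of criteria with leaf indicators.

fahp_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "fahp_error")))
}

#' Build and validate an indicator hierarchy
#'
#' Constructs the multi-level indicator tree used throughout the package: a
#' single target node at the root, one or more criterion layers below it, and
#' leaf indicators at the bottom. Every leaf carries a direction flag telling
#' the standardization step how to treat raw values.
#'
#' @param nodes Named list describing the tree. Names are node ids (e.g.
#'   `"A"`, `"B1"`, `"C11"`, `"D1"`); each element is a list with components
#'   `label` (free text, optional), and either `children` (character vector of
#'   child ids, for internal nodes) or `direction` (one of `"positive"`,
#'   `"reverse"`, `"graded"`, for leaves). An optional `weight` component
#'   gives the node's local weight among its siblings; weights can also be
#'   filled later from expert panels by [fahp()].
#' @param alternatives Character vector of alternative ids to be evaluated
#'   against the hierarchy (at least one).
#'
#' @details
#' Validation enforces the structural invariants of the model: ids are
#' unique, every child has exactly one parent, every node is reachable from
#' the single root (so the structure is a tree, not a graph with cycles),
#' leaves -- and only leaves -- carry a direction, and all leaves sit at the
#' same depth, as in a layered evaluation index system. Violations raise
#' classed conditions (`"fahp_duplicate_id"`, `"fahp_multiple_parents"`,
#' `"fahp_cycle"`, `"fahp_orphan"`, `"fahp_missing_direction"`,
#' `"fahp_depth"`, ...) so callers can distinguish failure modes.
#'
#' Leaf directions: `"positive"` means larger raw values are better,
#' `"reverse"` means smaller raw values are better (the value is negated
#' before min-max standardization), and `"graded"` marks qualitative
#' indicators whose values are already expert-assigned fractions in \[0, 1\]
#' and bypass threshold standardization.
#'
#' @return An object of class `"fahp_hierarchy"`: a list with components
#'   `nodes` (named list of node records with `id`, `label`, `parent`,
#'   `children`, `depth`, `direction`, `local_weight`), `root`, `leaves`
#'   (leaf ids in depth-first order) and `alternatives`.
#'
#' @examples
#' h <- build_hierarchy(
#'   nodes = list(
#'     A  = list(label = "target", children = c("B1", "B2")),
#'     B1 = list(label = "cost", direction = "reverse", weight = 0.4),
#'     B2 = list(label = "benefit", direction = "positive", weight = 0.6)
#'   ),
#'   alternatives = c("plan1", "plan2")
#' )
#' h
#' @seealso [read_hierarchy()], [composite_weights()], [fahp()]
#' @export
build_hierarchy <- function(nodes, alternatives) {
  if (!is.list(nodes) || length(nodes) == 0L || is.null(names(nodes)) ||
      any(!nzchar(names(nodes)))) {
    fahp_error("`nodes` must be a non-empty named list", "fahp_validation")
  }
  ids <- names(nodes)
  if (anyDuplicated(ids)) {
    fahp_error(sprintf("duplicate node id(s): %s",
                       paste(unique(ids[duplicated(ids)]), collapse = ", ")),
               "fahp_duplicate_id")
  }
  if (!is.character(alternatives) || length(alternatives) < 1L ||
      anyDuplicated(alternatives)) {
    fahp_error("`alternatives` must be a character vector of unique ids",
               "fahp_validation")
  }

  parent <- stats::setNames(rep(NA_character_, length(ids)), ids)
  for (id in ids) {
    kids <- nodes[[id]]$children
    if (is.null(kids)) next
    kids <- as.character(kids)
    if (anyDuplicated(kids)) {
      fahp_error(sprintf("node '%s' lists a duplicated child", id),
                 "fahp_duplicate_id")
    }
    for (k in kids) {
      if (k == id) fahp_error(sprintf("node '%s' is its own child", id), "fahp_cycle")
      if (!k %in% ids) {
        fahp_error(sprintf("child '%s' of node '%s' is not defined", k, id),
                   "fahp_unknown_node")
      }
      if (!is.na(parent[[k]])) {
        fahp_error(sprintf("node '%s' has more than one parent ('%s' and '%s')",
                           k, parent[[k]], id), "fahp_multiple_parents")
      }
      parent[[k]] <- id
    }
  }

  roots <- ids[is.na(parent)]
  if (length(roots) == 0L) fahp_error("no root node: the child relation is cyclic", "fahp_cycle")
  if (length(roots) > 1L) {
    fahp_error(sprintf("orphan node(s) not reachable from a single root: %s",
                       paste(roots[-1L], collapse = ", ")), "fahp_orphan")
  }
  root <- roots[[1L]]

  # depth-first walk from the root; anything unvisited is on a cycle island
  depth <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  order_visited <- character(0)
  stack <- list(list(id = root, d = 0L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    depth[[top$id]] <- top$d
    order_visited <- c(order_visited, top$id)
    kids <- as.character(nodes[[top$id]]$children %||% character(0))
    for (k in rev(kids)) stack[[length(stack) + 1L]] <- list(id = k, d = top$d + 1L)
  }
  if (anyNA(depth)) {
    fahp_error(sprintf("node(s) unreachable from root '%s': %s", root,
                       paste(ids[is.na(depth)], collapse = ", ")), "fahp_cycle")
  }

  recs <- list()
  for (id in ids) {
    spec <- nodes[[id]]
    kids <- as.character(spec$children %||% character(0))
    dir <- spec$direction
    if (length(kids) == 0L) {
      if (is.null(dir)) {
        fahp_error(sprintf("leaf '%s' has no direction", id), "fahp_missing_direction")
      }
      dir <- match.arg(dir, c("positive", "reverse", "graded"))
    } else if (!is.null(dir)) {
      fahp_error(sprintf("internal node '%s' must not carry a direction", id),
                 "fahp_validation")
    } else {
      dir <- NA_character_
    }
    w <- spec$weight %||% if (id == root) 1 else NA_real_
    recs[[id]] <- list(id = id, label = spec$label %||% id,
                       parent = parent[[id]], children = kids,
                       depth = depth[[id]], direction = dir,
                       local_weight = as.numeric(w))
  }

  leaves <- order_visited[vapply(recs[order_visited],
                                 function(n) length(n$children) == 0L, logical(1))]
  ld <- unique(vapply(recs[leaves], `[[`, integer(1), "depth"))
  if (length(ld) != 1L) {
    fahp_error("all leaves must lie at the same depth", "fahp_depth")
  }

  h <- structure(list(nodes = recs, root = root, leaves = leaves,
                      alternatives = as.character(alternatives)),
                 class = "fahp_hierarchy")
  check_sibling_weights(h)
  h
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# children's local weights, where present, must sum to 1
check_sibling_weights <- function(h) {
  for (n in h$nodes) {
    if (length(n$children) == 0L) next
    w <- vapply(h$nodes[n$children], `[[`, numeric(1), "local_weight")
    if (all(!is.na(w))) {
      if (any(w < 0)) fahp_error(
        sprintf("negative local weight under node '%s'", n$id), "fahp_validation")
      if (abs(sum(w) - 1) > 1e-6) fahp_error(
        sprintf("local weights of children of '%s' sum to %.6f, not 1", n$id, sum(w)),
        "fahp_validation")
    }
  }
  invisible(h)
}

#' @export
print.fahp_hierarchy <- function(x, ...) {
  tab <- table(vapply(x$nodes, `[[`, integer(1), "depth"))
  cat("Indicator hierarchy '", x$root, "': ", length(x$nodes), " nodes, ",
      length(x$leaves), " leaves\n", sep = "")
  cat("  nodes per level:", paste(sprintf("L%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  alternatives:", paste(x$alternatives, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.fahp_hierarchy <- function(x, ...) {
  data.frame(
    id = vapply(x$nodes, `[[`, character(1), "id"),
    label = vapply(x$nodes, `[[`, character(1), "label"),
    parent = vapply(x$nodes, `[[`, character(1), "parent"),
    depth = vapply(x$nodes, `[[`, integer(1), "depth"),
    direction = vapply(x$nodes, `[[`, character(1), "direction"),
    local_weight = vapply(x$nodes, `[[`, numeric(1), "local_weight"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Children of a hierarchy node
#'
#' @param h An `"fahp_hierarchy"`.
#' @param id Node id.
#' @return Character vector of child ids (empty for a leaf).
#' @export
hierarchy_children <- function(h, id) {
  stopifnot(inherits(h, "fahp_hierarchy"))
  if (!id %in% names(h$nodes)) fahp_error(sprintf("unknown node '%s'", id), "fahp_unknown_node")
  h$nodes[[id]]$children
}

#' Set the local weights of a node's children
#'
#' @param h An `"fahp_hierarchy"`.
#' @param id Id of the parent node whose children are weighted.
#' @param weights Numeric vector of positive weights summing to 1, in child
#'   order, or named by child id.
#' @return The updated hierarchy.
#' @export
set_local_weights <- function(h, id, weights) {
  stopifnot(inherits(h, "fahp_hierarchy"))
  kids <- hierarchy_children(h, id)
  if (length(kids) == 0L) fahp_error(sprintf("node '%s' is a leaf", id), "fahp_validation")
  w <- as.numeric(weights)
  if (!is.null(names(weights))) {
    if (!setequal(names(weights), kids)) {
      fahp_error(sprintf("weight names do not match the children of '%s'", id),
                 "fahp_validation")
    }
    w <- as.numeric(weights[kids])
  }
  if (length(w) != length(kids)) {
    fahp_error(sprintf("expected %d weights for node '%s'", length(kids), id),
               "fahp_validation")
  }
  if (any(w <= 0) || abs(sum(w) - 1) > 1e-6) {
    fahp_error("weights must be positive and sum to 1", "fahp_validation")
  }
  for (i in seq_along(kids)) h$nodes[[kids[i]]]$local_weight <- w[i]
  h
}

#' Read / write a hierarchy configuration file
#'
#' The on-disk dialect is a YAML mapping with two top-level keys:
#' `alternatives` (sequence of ids) and `nodes` (mapping of node id to
#' `{label, children | direction, weight}`), i.e. the same structure
#' [build_hierarchy()] takes. `format: 1` is written for versioning and
#' checked on read.
#'
#' @param file Path to the YAML file.
#' @return `read_hierarchy()` returns an `"fahp_hierarchy"`;
#'   `write_hierarchy()` returns `file` invisibly.
#' @export
read_hierarchy <- function(file) {
  spec <- yaml::read_yaml(file)
  if (!is.null(spec$format) && spec$format != 1L) {
    fahp_error(sprintf("unsupported hierarchy file format '%s'", spec$format),
               "fahp_validation")
  }
  build_hierarchy(spec$nodes, unlist(spec$alternatives))
}

#' @rdname read_hierarchy
#' @param h An `"fahp_hierarchy"` to serialize.
#' @export
write_hierarchy <- function(h, file) {
  stopifnot(inherits(h, "fahp_hierarchy"))
  nodes <- lapply(h$nodes, function(n) {
    out <- list(label = n$label)
    if (length(n$children)) out$children <- as.list(n$children) else out$direction <- n$direction
    if (!is.na(n$local_weight) && n$id != h$root) out$weight <- n$local_weight
    out
  })
  yaml::write_yaml(list(format = 1L, alternatives = as.list(h$alternatives),
                        nodes = nodes), file, precision = 12L)
  invisible(file)
}
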