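#' Labelled weighted causal DAG
#'
#' Container for a causal directed acyclic graph over named variables.  An
#' edge `i -> j` is present wherever `W[i, j] != 0`; the weight is the
#' standardized direct effect of `i` on `j` (SD per SD when the data are
#' standardized).  Nodes may optionally carry one of the study's variable
#' categories (`emotion_before`, `behavior`, `trip_factor`, `predetermined`,
#' `emotion_after`), which downstream code uses for grouping and for the
#' temporal forbidden-edge policy.
#'
#' @param W square numeric matrix of edge weights; `W[i, j]` is the direct
#'   effect of node `i` on node `j`.  The nonzero support must be acyclic.
#' @param labels character vector of unique node names; defaults to the
#'   column names of `W`.
#' @param categories optional named character vector mapping every label to
#'   a variable category.
#' @return An object of class `causal_dag`.
#' @examples
#' W <- matrix(0, 3, 3, dimnames = rep(list(c("Z", "X", "Y")), 2))
#' W["Z", "X"] <- 0.5; W["Z", "Y"] <- 0.5; W["X", "Y"] <- 0.3
#' g <- causal_dag(W)
#' dag_edges(g)
#' @export
causal_dag <- function(W, labels = colnames(W), categories = NULL) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("`W` must be a square matrix")
  d <- nrow(W)
  if (is.null(labels)) labels <- paste0("V", seq_len(d))
  if (length(labels) != d || anyDuplicated(labels))
    stop("`labels` must be ", d, " unique node names")
  dimnames(W) <- list(labels, labels)
  if (any(diag(W) != 0)) stop("self-loops are not allowed")
  ord <- topological_order(W != 0)
  if (is.null(ord))
    stop("the nonzero support of `W` contains a directed cycle")
  if (!is.null(categories)) {
    categories <- check_categories(categories, labels)
  }
  structure(
    list(labels = labels, W = W, categories = categories,
         topo_order = labels[ord]),
    class = "causal_dag"
  )
}

#' @export
print.causal_dag <- function(x, ...) {
  e <- dag_edges(x)
  cat(sprintf("causal_dag: %d nodes, %d edges\n",
              length(x$labels), nrow(e)))
  if (nrow(e) > 0) {
    for (i in seq_len(nrow(e)))
      cat(sprintf("  %s -> %s  (%.3f)\n", e$from[i], e$to[i], e$weight[i]))
  }
  invisible(x)
}

#' Edge list of a causal DAG
#'
#' @param dag a [causal_dag()].
#' @return data.frame with columns `from`, `to`, `weight`, ordered by the
#'   graph's topological order (then by target label).
#' @export
dag_edges <- function(dag) {
  stopifnot(inherits(dag, "causal_dag"))
  idx <- which(dag$W != 0, arr.ind = TRUE)
  out <- data.frame(
    from = dag$labels[idx[, 1]],
    to = dag$labels[idx[, 2]],
    weight = dag$W[idx],
    stringsAsFactors = FALSE
  )
  o <- order(match(out$from, dag$topo_order), match(out$to, dag$topo_order))
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname dag_edges
#' @export
n_edges <- function(dag) nrow(dag_edges(dag))

# ---- internal graph primitives (logical adjacency A[i, j] = i -> j) --------

# Kahn's algorithm; returns an index ordering or NULL if cyclic.
topological_order <- function(A) {
  d <- nrow(A)
  indeg <- colSums(A)
  queue <- which(indeg == 0)
  ord <- integer(0)
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    ord <- c(ord, v)
    ch <- which(A[v, ])
    for (u in ch) {
      indeg[u] <- indeg[u] - 1
      if (indeg[u] == 0) queue <- c(queue, u)
    }
    A[v, ] <- FALSE
  }
  if (length(ord) < d) NULL else ord
}

node_index <- function(dag, x) {
  i <- match(x, dag$labels)
  if (anyNA(i)) stop("unknown node label(s): ", paste(x[is.na(i)], collapse = ", "))
  i
}

# all nodes reachable from i by directed edges (excluding i itself)
descendants_idx <- function(A, i) {
  seen <- rep(FALSE, nrow(A))
  frontier <- which(A[i, ])
  while (length(frontier) > 0) {
    v <- frontier[1]; frontier <- frontier[-1]
    if (!seen[v]) {
      seen[v] <- TRUE
      frontier <- c(frontier, which(A[v, ]))
    }
  }
  which(seen)
}

ancestors_idx <- function(A, set) {
  seen <- rep(FALSE, nrow(A))
  frontier <- set
  while (length(frontier) > 0) {
    v <- frontier[1]; frontier <- frontier[-1]
    pa <- which(A[, v])
    for (p in pa) if (!seen[p]) { seen[p] <- TRUE; frontier <- c(frontier, p) }
  }
  which(seen)
}

#' Descendants of a node
#'
#' @param dag a [causal_dag()].
#' @param node a node label.
#' @return character vector of strict descendants (possibly empty).
#' @export
dag_descendants <- function(dag, node) {
  i <- node_index(dag, node)
  dag$labels[descendants_idx(dag$W != 0, i)]
}

# ---- d-separation ----------------------------------------------------------

#' Test d-separation in a DAG
#'
#' Decides whether `x` and `y` are d-separated given the conditioning set
#' `given`: every undirected path between them must be blocked.  A chain or
#' fork is blocked when its middle node is conditioned on; a collider is
#' blocked unless the collider or one of its descendants is conditioned on.
#' Implemented as a reachability search over (node, direction) states, which
#' visits each directed edge at most twice; the test suite checks it against
#' a brute-force path-enumeration oracle on exhaustive small-graph suites.
#'
#' @param dag a [causal_dag()].
#' @param x,y distinct node labels.
#' @param given character vector of conditioning labels (may be empty); must
#'   exclude `x` and `y`.
#' @return `TRUE` if `x` and `y` are d-separated given `given`.
#' @examples
#' W <- matrix(0, 3, 3, dimnames = rep(list(c("X", "M", "Y")), 2))
#' W["X", "M"] <- 1; W["M", "Y"] <- 1
#' d_separated(causal_dag(W), "X", "Y", "M")  # chain blocked by its middle
#' @export
d_separated <- function(dag, x, y, given = character(0)) {
  stopifnot(inherits(dag, "causal_dag"))
  xi <- node_index(dag, x)
  yi <- node_index(dag, y)
  if (xi == yi) stop("`x` and `y` must be distinct")
  zi <- if (length(given) > 0) node_index(dag, given) else integer(0)
  if (xi %in% zi || yi %in% zi)
    stop("`given` must not contain `x` or `y`")
  A <- dag$W != 0
  !reachable_active(A, xi, yi, zi)
}

# TRUE if y is reachable from x along an active trail given Z.
# States are (node, direction): "up" = the trail may continue in any
# direction (we arrived from a child, or we are at the source); "down" = we
# arrived from a parent, so we may only continue to children, or to parents
# if the node is an ancestor of Z (active collider).
reachable_active <- function(A, x, y, z) {
  d <- nrow(A)
  inZ <- rep(FALSE, d); inZ[z] <- TRUE
  ancZ <- rep(FALSE, d)
  ancZ[z] <- TRUE
  ancZ[ancestors_idx(A, z)] <- TRUE
  visited_up <- rep(FALSE, d)
  visited_down <- rep(FALSE, d)
  frontier <- list(c(x, 1L))  # 1 = up, 2 = down
  while (length(frontier) > 0) {
    st <- frontier[[1]]; frontier <- frontier[-1]
    v <- st[1]; dir <- st[2]
    if (dir == 1L) {
      if (visited_up[v]) next
      visited_up[v] <- TRUE
      if (!inZ[v]) {
        if (v == y) return(TRUE)
        for (p in which(A[, v])) frontier <- c(frontier, list(c(p, 1L)))
        for (ch in which(A[v, ])) frontier <- c(frontier, list(c(ch, 2L)))
      }
    } else {
      if (visited_down[v]) next
      visited_down[v] <- TRUE
      if (!inZ[v]) {
        if (v == y) return(TRUE)
        for (ch in which(A[v, ])) frontier <- c(frontier, list(c(ch, 2L)))
      }
      if (ancZ[v]) {
        for (p in which(A[, v])) frontier <- c(frontier, list(c(p, 1L)))
      }
    }
  }
  FALSE
}

# ---- backdoor criterion ----------------------------------------------------

#' Enumerate backdoor adjustment sets
#'
#' A set `Z` satisfies the backdoor criterion for the ordered pair
#' `(x, y)` when (i) `Z` contains no descendant of `x` and (ii) `Z` blocks
#' every path between `x` and `y` that enters `x` through an incoming edge.
#' Condition (ii) is tested as d-separation of `x` and `y` given `Z` in the
#' graph with all edges out of `x` removed.  Adjusting for such a `Z` in a
#' linear model identifies the total causal effect of `x` on `y`.
#'
#' @param dag a [causal_dag()].
#' @param x,y distinct node labels (cause and outcome).
#' @param max_size largest set size to consider; defaults to all nodes
#'   except `x` and `y` (complete enumeration at this problem's scale).
#' @return A list of [adjustment sets][minimal_backdoor_set] sorted by size,
#'   then lexicographically; empty when no valid set of size `<= max_size`
#'   exists.
#' @export
backdoor_sets <- function(dag, x, y, max_size = length(dag$labels) - 2L) {
  stopifnot(inherits(dag, "causal_dag"))
  xi <- node_index(dag, x)
  yi <- node_index(dag, y)
  if (xi == yi) stop("`x` and `y` must be distinct")
  A <- dag$W != 0
  de_x <- descendants_idx(A, xi)
  candidates <- setdiff(seq_along(dag$labels), c(xi, yi, de_x))
  candidates <- candidates[order(dag$labels[candidates])]
  # backdoor graph: remove edges out of x
  Abd <- A
  Abd[xi, ] <- FALSE
  out <- list()
  min_found <- NA_integer_
  for (k in 0:min(max_size, length(candidates))) {
    # index-based combn: a length-1 numeric x would otherwise mean seq_len(x)
    sets_k <- if (k == 0) list(integer(0)) else
      lapply(utils::combn(seq_along(candidates), k, simplify = FALSE),
             function(ii) candidates[ii])
    for (z in sets_k) {
      if (!reachable_active(Abd, xi, yi, z)) {
        if (is.na(min_found)) min_found <- k
        out[[length(out) + 1L]] <- new_adjustment_set(
          x, y, sort(dag$labels[z]), minimal = (k == min_found))
      }
    }
  }
  # sort by size then lexicographically on the joined labels
  if (length(out) > 1) {
    key <- vapply(out, function(s) paste(s$set, collapse = "\001"), "")
    sz <- vapply(out, function(s) length(s$set), 0L)
    out <- out[order(sz, key)]
  }
  out
}

new_adjustment_set <- function(source, target, set, minimal = FALSE) {
  structure(
    list(source = source, target = target,
         set = as.character(set), minimal = isTRUE(minimal)),
    class = "adjustment_set"
  )
}

#' @export
print.adjustment_set <- function(x, ...) {
  cat(sprintf("adjustment set for %s -> %s: {%s}%s\n",
              x$source, x$target,
              paste(x$set, collapse = ", "),
              if (x$minimal) " [minimal]" else ""))
  invisible(x)
}

#' Smallest backdoor adjustment set
#'
#' Returns the smallest set satisfying the backdoor criterion for
#' `(x, y)`, breaking size ties lexicographically on the sorted labels, so
#' the choice is deterministic.
#'
#' @inheritParams backdoor_sets
#' @return An `adjustment_set` object with fields `source`, `target`, `set`
#'   and `minimal = TRUE`.
#' @seealso [backdoor_sets()]
#' @export
minimal_backdoor_set <- function(dag, x, y,
                                 max_size = length(dag$labels) - 2L) {
  stopifnot(inherits(dag, "causal_dag"))
  xi <- node_index(dag, x)
  yi <- node_index(dag, y)
  if (xi == yi) stop("`x` and `y` must be distinct")
  A <- dag$W != 0
  de_x <- descendants_idx(A, xi)
  candidates <- setdiff(seq_along(dag$labels), c(xi, yi, de_x))
  candidates <- candidates[order(dag$labels[candidates])]
  Abd <- A
  Abd[xi, ] <- FALSE
  # size-increasing search; combn over label-sorted candidates makes the
  # first hit the lexicographically smallest set of minimal size
  for (k in 0:min(max_size, length(candidates))) {
    sets_k <- if (k == 0) list(integer(0)) else
      lapply(utils::combn(seq_along(candidates), k, simplify = FALSE),
             function(ii) candidates[ii])
    for (z in sets_k) {
      if (!reachable_active(Abd, xi, yi, z))
        return(new_adjustment_set(x, y, sort(dag$labels[z]),
                                  minimal = TRUE))
    }
  }
  stop(errorCondition(
    sprintf("no backdoor adjustment set exists for %s -> %s; the effect is not backdoor-identifiable in this graph", x, y),
    class = c("tripcausal_identification_error", "error", "condition")))
}

check_categories <- function(categories, labels) {
  allowed <- c("emotion_before", "behavior", "trip_factor",
               "predetermined", "emotion_after")
  if (is.null(names(categories)) || !setequal(names(categories), labels))
    stop("`categories` must be a named vector covering every node label")
  bad <- setdiff(unique(categories), allowed)
  if (length(bad) > 0)
    stop("unknown categories: ", paste(bad, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")")
  categories[labels]
}
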