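# Brute-force oracles for d-separation and the backdoor criterion.
# These operate on plain logical adjacency matrices (A[i, j] = i -> j) and
# share no code with the package's reachability implementation: paths are
# enumerated explicitly and the blocking rules applied per path.

# all simple paths between x and y in the undirected skeleton, as integer
# node sequences
enumerate_paths <- function(A, x, y) {
  d <- nrow(A)
  skel <- A | t(A)
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == y) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (u in which(skel[v, ])) {
      if (!(u %in% path)) walk(c(path, u))
    }
  }
  walk(x)
  paths
}

oracle_descendants <- function(A, i) {
  d <- nrow(A)
  reach <- rep(FALSE, d)
  frontier <- which(A[i, ])
  while (length(frontier)) {
    v <- frontier[1]; frontier <- frontier[-1]
    if (!reach[v]) { reach[v] <- TRUE; frontier <- c(frontier, which(A[v, ])) }
  }
  which(reach)
}

# is the given path active (not blocked) given conditioning set z?
path_active <- function(A, path, z) {
  k <- length(path)
  if (k <= 2) return(TRUE)
  for (i in 2:(k - 1)) {
    prev <- path[i - 1]; v <- path[i]; nxt <- path[i + 1]
    collider <- A[prev, v] && A[nxt, v]
    if (collider) {
      opened <- (v %in% z) || any(oracle_descendants(A, v) %in% z)
      if (!opened) return(FALSE)
    } else {
      if (v %in% z) return(FALSE)
    }
  }
  TRUE
}

oracle_dsep <- function(A, x, y, z) {
  paths <- enumerate_paths(A, x, y)
  for (p in paths) if (path_active(A, p, z)) return(FALSE)
  TRUE
}

# backdoor validity by direct definition: z has no descendant of x, and
# every path whose first edge points into x is blocked given z
oracle_backdoor_valid <- function(A, x, y, z) {
  if (x %in% z || y %in% z) return(FALSE)
  if (any(z %in% oracle_descendants(A, x))) return(FALSE)
  paths <- enumerate_paths(A, x, y)
  for (p in paths) {
    if (!A[p[2], p[1]]) next       # first edge leaves x: not a backdoor path
    if (path_active(A, p, z)) return(FALSE)
  }
  TRUE
}

oracle_backdoor_sets <- function(A, x, y, max_size = nrow(A) - 2L) {
  cand <- setdiff(seq_len(nrow(A)), c(x, y))
  out <- list()
  for (k in 0:min(max_size, length(cand))) {
    sets_k <- if (k == 0) list(integer(0)) else
      lapply(utils::combn(seq_along(cand), k, simplify = FALSE),
             function(ii) cand[ii])
    for (z in sets_k) if (oracle_backdoor_valid(A, x, y, z))
      out[[length(out) + 1L]] <- sort(z)
  }
  out
}

# every directed graph on `d` labelled nodes with at most one edge per
# unordered pair (3 states per pair), filtered to the acyclic ones
all_dags <- function(d) {
  pairs <- utils::combn(d, 2)
  npair <- ncol(pairs)
  out <- list()
  for (code in 0:(3^npair - 1)) {
    A <- matrix(FALSE, d, d)
    c0 <- code
    for (p in seq_len(npair)) {
      s <- c0 %% 3; c0 <- c0 %/% 3
      i <- pairs[1, p]; j <- pairs[2, p]
      if (s == 1) A[i, j] <- TRUE
      if (s == 2) A[j, i] <- TRUE
    }
    if (is_acyclic_adj(A)) out[[length(out) + 1L]] <- A
  }
  out
}

is_acyclic_adj <- function(A) {
  d <- nrow(A)
  indeg <- colSums(A)
  removed <- rep(FALSE, d)
  repeat {
    src <- which(!removed & indeg == 0)
    if (length(src) == 0) break
    for (v in src) {
      removed[v] <- TRUE
      ch <- which(A[v, ])
      indeg[ch] <- indeg[ch] - 1
    }
  }
  all(removed)
}

random_dag_adj <- function(d, n_edges, seed) {
  set.seed(seed)
  perm <- sample(d)
  pairs <- t(utils::combn(d, 2))
  pick <- sample(nrow(pairs), min(n_edges, nrow(pairs)))
  A <- matrix(FALSE, d, d)
  for (k in pick) A[perm[pairs[k, 1]], perm[pairs[k, 2]]] <- TRUE
  A
}

adj_to_dag <- function(A, labels = NULL) {
  d <- nrow(A)
  if (is.null(labels)) labels <- sprintf("n%02d", seq_len(d))
  W <- matrix(0, d, d, dimnames = list(labels, labels))
  W[A] <- 1
  causal_dag(W)
}

# all subsets of an index vector, as a list (including the empty set)
all_subsets <- function(v) {
  out <- list(integer(0))
  for (x in v) out <- c(out, lapply(out, function(s) c(s, x)))
  out
}
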