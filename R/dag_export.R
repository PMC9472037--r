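#' Convert a causal DAG to an igraph object
#'
#' @param dag a [causal_dag()].
#' @return weighted directed `igraph` graph; node categories (if any) are
#'   kept as a vertex attribute.
#' @export
as_igraph <- function(dag) {
  stopifnot(inherits(dag, "causal_dag"))
  g <- igraph::graph_from_adjacency_matrix(dag$W, mode = "directed",
                                           weighted = TRUE)
  if (!is.null(dag$categories))
    igraph::V(g)$category <- unname(dag$categories[igraph::V(g)$name])
  g
}

#' Export a causal DAG
#'
#' `write_dag_csv()` writes the edge list (`source`, `target`, `weight`);
#' `write_dag_graphml()` and `write_dag_dot()` write GraphML and DOT via
#' igraph.
#'
#' @param dag a [causal_dag()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_dag_csv <- function(dag, path) {
  e <- dag_edges(dag)
  names(e) <- c("source", "target", "weight")
  utils::write.csv(e, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dag_csv
#' @export
write_dag_graphml <- function(dag, path) {
  igraph::write_graph(as_igraph(dag), path, format = "graphml")
  invisible(path)
}

#' @rdname write_dag_csv
#' @export
write_dag_dot <- function(dag, path) {
  igraph::write_graph(as_igraph(dag), path, format = "dot")
  invisible(path)
}

#' Read a causal DAG from an edge-list CSV
#'
#' @param path CSV with columns `source`, `target`, `weight`.
#' @param labels node labels; defaults to the labels appearing in the
#'   file, sorted.
#' @param categories optional category vector.
#' @return a [causal_dag()].
#' @export
read_dag_csv <- function(path, labels = NULL, categories = NULL) {
  e <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("source", "target", "weight") %in% names(e)))
    stop("DAG CSV must have columns source, target, weight")
  if (is.null(labels)) labels <- sort(unique(c(e$source, e$target)))
  W <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  W[cbind(match(e$source, labels), match(e$target, labels))] <- e$weight
  causal_dag(W, labels = labels, categories = categories)
}
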