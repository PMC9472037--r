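#' Temporally impossible edges for the study's variable categories
#'
#' The study variables fall into stages along the timeline of a trip:
#' predetermined factors are fixed before departure, before-driving emotions
#' are measured at departure, driving behavior and trip-dependent factors
#' arise during the trip, and after-driving emotions are measured at
#' arrival.  Edges that would run backwards in time are excluded a priori
#' from structure learning:
#'
#' * nothing causes a predetermined factor (including other predetermined
#'   factors, which are treated as exogenous);
#' * an after-driving emotion causes no earlier-stage variable;
#' * driving behavior and trip-dependent factors do not cause
#'   before-driving emotions.
#'
#' @param categories named character vector mapping node labels to one of
#'   `emotion_before`, `behavior`, `trip_factor`, `predetermined`,
#'   `emotion_after`.
#' @return data.frame with columns `from`, `to` (class
#'   `forbidden_edge_set`), one row per forbidden ordered pair.
#' @examples
#' cats <- c(sun = "predetermined", before_arousal = "emotion_before",
#'           steering = "behavior", after_arousal = "emotion_after")
#' temporal_forbidden_set(cats)
#' @export
temporal_forbidden_set <- function(categories) {
  labels <- names(categories)
  categories <- check_categories(categories, labels)
  from <- character(0); to <- character(0)
  for (i in labels) for (j in labels) {
    if (i == j) next
    ci <- categories[[i]]; cj <- categories[[j]]
    forb <- cj == "predetermined" ||
      (ci == "emotion_after" && cj != "emotion_after") ||
      (ci %in% c("behavior", "trip_factor") && cj == "emotion_before")
    if (forb) { from <- c(from, i); to <- c(to, j) }
  }
  out <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("forbidden_edge_set", "data.frame")
  out
}

#' Forbidden-edge mask matrix
#'
#' Converts a forbidden-edge set (or a category vector, via
#' [temporal_forbidden_set()]) into the logical matrix consumed by
#' [notears_fit()]: `TRUE` at `[i, j]` means the directed edge `i -> j` is
#' disallowed and its weight is held at exactly zero.
#'
#' @param forbidden a `forbidden_edge_set` data.frame (columns `from`,
#'   `to`) or a named category vector.
#' @param labels node labels defining the matrix dimensions and order.
#' @return logical `length(labels)` x `length(labels)` matrix.
#' @export
forbidden_mask <- function(forbidden, labels) {
  if (!is.data.frame(forbidden) && !is.null(names(forbidden)))
    forbidden <- temporal_forbidden_set(forbidden)
  M <- matrix(FALSE, length(labels), length(labels),
              dimnames = list(labels, labels))
  if (nrow(forbidden) > 0) {
    i <- match(forbidden$from, labels)
    j <- match(forbidden$to, labels)
    if (anyNA(i) || anyNA(j))
      stop("forbidden edges reference unknown node labels")
    M[cbind(i, j)] <- TRUE
  }
  M
}
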