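#' Robustness test: re-estimate after adding a random confounder
#'
#' Draws an independent standard-normal column, appends it to the
#' adjustment set, and re-runs the adjusted regression.  Because the added
#' column is independent of every variable in the model, the population
#' coefficient of the source is unchanged; the finite-sample change
#' shrinks as O(1/n).  A difference close to 0 therefore indicates an
#' estimate that is robust to this perturbation of the model; a large
#' difference flags fragility to misspecification.  The reported delta is
#' the mean over `n_repeats` independent draws (a single draw is noisy).
#'
#' @param table data.frame of standardized trips.
#' @param x,y source and target column names.
#' @param adjust adjustment covariates (character vector or
#'   `adjustment_set`).
#' @param seed integer seed making the confounder draws reproducible.
#' @param n_repeats number of independent confounder draws (default 20).
#' @param conf_level passed to [estimate_effect()].
#' @return list of class `refutation`: `delta` (mean of new minus
#'   original estimate, sign preserved), `deltas` (per-draw), `original`
#'   and `new_mean` (estimates), `n_repeats`.
#' @export
refute_random_confounder <- function(table, x, y, adjust = character(0),
                                     seed = NULL, n_repeats = 20,
                                     conf_level = 0.95) {
  if (inherits(adjust, "adjustment_set")) adjust <- adjust$set
  stopifnot(n_repeats >= 1)
  orig <- estimate_effect(table, x, y, adjust = adjust,
                          conf_level = conf_level)
  if (!is.null(seed)) set.seed(seed)
  confounder_col <- ".random_confounder"
  while (confounder_col %in% names(table))
    confounder_col <- paste0(confounder_col, "_")
  deltas <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    tbl <- table
    tbl[[confounder_col]] <- stats::rnorm(nrow(table))
    new <- estimate_effect(tbl, x, y, adjust = c(adjust, confounder_col),
                           conf_level = conf_level)
    deltas[r] <- new$ce - orig$ce
  }
  structure(
    list(delta = mean(deltas), deltas = deltas, original = orig$ce,
         new_mean = orig$ce + mean(deltas), n_repeats = n_repeats),
    class = "refutation"
  )
}

#' @export
print.refutation <- function(x, ...) {
  cat(sprintf(
    "random-confounder refutation: original %.4f, mean change %+.2g over %d draws\n",
    x$original, x$delta, x$n_repeats))
  invisible(x)
}

#' Fill the robustness column of an effect table
#'
#' Runs [refute_random_confounder()] for every identifiable row of an
#' effect table, with per-row seeds derived deterministically from `seed`.
#'
#' @param effects data.frame from [effect_table()].
#' @param table the standardized trip table the effects were estimated on.
#' @param seed integer base seed.
#' @param n_repeats confounder draws per edge.
#' @return `effects` with `robustness_delta` filled in.
#' @export
add_robustness <- function(effects, table, seed = NULL, n_repeats = 20) {
  for (i in seq_len(nrow(effects))) {
    if (!isTRUE(effects$identifiable[i])) next
    adj <- effects$adjustment_set[i]
    adj <- if (is.na(adj) || adj == "") character(0) else
      strsplit(adj, ";", fixed = TRUE)[[1]]
    row_seed <- if (is.null(seed)) NULL else (seed + i) %% .Machine$integer.max
    ref <- refute_random_confounder(
      table, effects$source[i], effects$target[i], adjust = adj,
      seed = row_seed, n_repeats = n_repeats)
    effects$robustness_delta[i] <- ref$delta
  }
  effects
}
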