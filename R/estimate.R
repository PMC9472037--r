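#' Estimate a standardized causal effect by adjusted regression
#'
#' Ordinary least squares of the target on the source plus its backdoor
#' adjustment set (with intercept).  On standardized data the source
#' coefficient is the total causal effect in SD units: the change in the
#' target, in SDs, caused by a 1-SD change in the source.  The confidence
#' interval and two-sided p-value come from the coefficient's standard
#' error and the t distribution with `n - |Z| - 2` residual degrees of
#' freedom.
#'
#' @param table data.frame of standardized trips.
#' @param x,y source and target column names.
#' @param adjust adjustment covariates: a character vector or an
#'   `adjustment_set` from [minimal_backdoor_set()].
#' @param conf_level confidence level for the interval (default 0.95).
#' @return one-row data.frame of class `causal_estimate` with columns
#'   `source`, `target`, `ce`, `ci_low`, `ci_high`, `p_value`,
#'   `adjustment_set` (semicolon-joined), `n`, `robustness_delta` (`NA`
#'   until filled by [refute_random_confounder()]).
#' @examples
#' set.seed(1)
#' z <- rnorm(500); x <- 0.5 * z + rnorm(500, sd = sqrt(0.75))
#' y <- 0.5 * z + 0.3 * x + rnorm(500, sd = 0.7)
#' estimate_effect(data.frame(x, y, z), "x", "y", adjust = "z")
#' @export
estimate_effect <- function(table, x, y, adjust = character(0),
                            conf_level = 0.95) {
  if (inherits(adjust, "adjustment_set")) adjust <- adjust$set
  adjust <- sort(unique(as.character(adjust)))
  vars <- c(y, x, adjust)
  missing_cols <- setdiff(vars, names(table))
  if (length(missing_cols) > 0)
    stop("column(s) not in table: ", paste(missing_cols, collapse = ", "))
  if (x %in% adjust || y %in% adjust)
    stop("the adjustment set must not contain the source or target")
  df <- table[, vars, drop = FALSE]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  if (n <= length(adjust) + 2)
    stop("need more than |adjustment set| + 2 complete rows (have ", n, ")")
  rhs <- paste(sprintf("`%s`", c(x, adjust)), collapse = " + ")
  fml <- stats::as.formula(sprintf("`%s` ~ %s", y, rhs))
  fit <- stats::lm(fml, data = df)
  co <- stats::coef(fit)
  if (anyNA(co)) {
    bad <- names(co)[is.na(co)]
    stop("rank-deficient design; collinear column(s): ",
         paste(gsub("`", "", bad), collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  xn <- sprintf("`%s`", x)
  if (!xn %in% rownames(sm)) xn <- x
  ce <- sm[xn, "Estimate"]
  se <- sm[xn, "Std. Error"]
  dof <- fit$df.residual
  tq <- stats::qt(1 - (1 - conf_level) / 2, dof)
  p <- 2 * stats::pt(abs(ce / se), dof, lower.tail = FALSE)
  out <- data.frame(
    source = x, target = y, ce = unname(ce),
    ci_low = unname(ce - tq * se), ci_high = unname(ce + tq * se),
    p_value = unname(p),
    adjustment_set = paste(adjust, collapse = ";"),
    n = n, robustness_delta = NA_real_,
    stringsAsFactors = FALSE
  )
  class(out) <- c("causal_estimate", "data.frame")
  out
}

#' Estimate all edge effects of a causal DAG
#'
#' One adjusted regression per directed edge of the graph, each using the
#' edge's minimal backdoor adjustment set, assembled into the analysis's
#' effect table.  Rows are grouped by the variable-category pairing of
#' source and target (emotions on driving behavior, driving behavior on
#' emotions, predetermined factors on emotions, trip-dependent factors on
#' emotions, emotions on emotions, then remaining pairings); within a
#' group, rows follow the graph's topological order.  An edge whose effect
#' is not backdoor-identifiable under `max_size` is retained with `NA`
#' estimates and `identifiable = FALSE`.
#'
#' @param table data.frame of standardized trips.
#' @param dag a [causal_dag()], learned or supplied.
#' @param conf_level confidence level for the intervals.
#' @param alpha significance level for the `significant` flag
#'   (default 0.05, on raw p-values).
#' @param p_adjust `"none"` (default, raw p-values) or `"BH"` for a
#'   Benjamini-Hochberg correction before flagging significance.
#' @param max_size passed to [backdoor_sets()].
#' @return data.frame with one row per edge: the [estimate_effect()]
#'   columns plus `group`, `significant` and `identifiable`.
#' @export
effect_table <- function(table, dag, conf_level = 0.95, alpha = 0.05,
                         p_adjust = c("none", "BH"),
                         max_size = length(dag$labels) - 2L) {
  stopifnot(inherits(dag, "causal_dag"))
  p_adjust <- match.arg(p_adjust)
  e <- dag_edges(dag)
  rows <- vector("list", nrow(e))
  if (nrow(e) > 0) {
    for (i in seq_len(nrow(e))) {
      x <- e$from[i]; y <- e$to[i]
      row <- tryCatch({
        adj <- minimal_backdoor_set(dag, x, y, max_size = max_size)
        est <- estimate_effect(table, x, y, adjust = adj,
                               conf_level = conf_level)
        est$identifiable <- TRUE
        est
      }, tripcausal_identification_error = function(cnd) {
        data.frame(source = x, target = y, ce = NA_real_,
                   ci_low = NA_real_, ci_high = NA_real_,
                   p_value = NA_real_, adjustment_set = NA_character_,
                   n = nrow(table), robustness_delta = NA_real_,
                   identifiable = FALSE, stringsAsFactors = FALSE)
      })
      rows[[i]] <- row
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(source = character(0), target = character(0),
                      ce = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0), p_value = numeric(0),
                      adjustment_set = character(0), n = integer(0),
                      robustness_delta = numeric(0),
                      identifiable = logical(0),
                      group = character(0), significant = logical(0))
    class(out) <- c("causal_estimate", "data.frame")
    return(out)
  }
  out$group <- edge_group(dag, out$source, out$target)
  o <- order(match(out$group, group_order()),
             match(out$source, dag$topo_order),
             match(out$target, dag$topo_order))
  out <- out[o, , drop = FALSE]
  p <- out$p_value
  if (p_adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  out$significant <- !is.na(p) & p < alpha
  rownames(out) <- NULL
  class(out) <- c("causal_estimate", "data.frame")
  out
}

group_order <- function() {
  c("emotions on driving behavior",
    "driving behavior on emotions",
    "predetermined factors on emotions",
    "trip-dependent factors on emotions",
    "emotions on emotions")
}

edge_group <- function(dag, from, to) {
  if (is.null(dag$categories)) return(rep("effects", length(from)))
  fam <- c(emotion_before = "emotions", emotion_after = "emotions",
           behavior = "driving behavior",
           trip_factor = "trip-dependent factors",
           predetermined = "predetermined factors")
  paste(fam[dag$categories[from]], "on", fam[dag$categories[to]])
}

#' Write an effect table as CSV
#'
#' The machine-readable analogue of the published results table: columns
#' `source`, `target`, `ce`, `ci_low`, `ci_high`, `p_value`,
#' `adjustment_set`, `robustness_delta` plus the grouping/flags.
#'
#' @param effects data.frame from [effect_table()].
#' @param path file path.
#' @export
write_effect_table <- function(effects, path) {
  utils::write.csv(as.data.frame(effects), path, row.names = FALSE)
  invisible(path)
}
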