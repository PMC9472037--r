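#' Standardize trip-table columns to mean 0, SD 1
#'
#' Centers and scales each requested column with the sample SD (n - 1
#' convention).  The returned parameters allow the exact inverse transform;
#' re-applying `standardize()` to an already standardized table is a
#' no-op up to floating error.  Binary 0/1 columns are standardized like
#' continuous ones by default, so that all effects downstream are in SD
#' units; set `standardize_binary = FALSE` to leave them on their raw
#' scale.
#'
#' @param table a data.frame of trips.
#' @param columns columns to standardize; defaults to every numeric
#'   column.
#' @param standardize_binary if `FALSE`, columns containing only 0/1 (and
#'   `NA`) are left untouched.
#' @return list with elements `data` (the transformed table, scale flag
#'   `"standardized"`) and `params` (data.frame `column`, `mean`, `sd`).
#' @examples
#' s <- standardize(data.frame(x = c(0, 10)))
#' s$data$x  # -0.707, 0.707
#' @export
standardize <- function(table, columns = NULL, standardize_binary = TRUE) {
  stopifnot(is.data.frame(table))
  if (is.null(columns))
    columns <- names(table)[vapply(table, is.numeric, TRUE)]
  missing_cols <- setdiff(columns, names(table))
  if (length(missing_cols) > 0)
    stop("unknown column(s): ", paste(missing_cols, collapse = ", "))
  if (!standardize_binary) {
    is_bin <- vapply(columns, function(cn) {
      v <- table[[cn]]
      all(v[!is.na(v)] %in% c(0, 1))
    }, TRUE)
    columns <- columns[!is_bin]
  }
  means <- numeric(0); sds <- numeric(0)
  out <- table
  for (cn in columns) {
    v <- table[[cn]]
    if (!is.numeric(v)) stop("column '", cn, "' is not numeric")
    vv <- v[!is.na(v)]
    if (length(vv) == 0) stop("column '", cn, "' is entirely missing")
    m <- mean(vv); s <- stats::sd(vv)
    if (!is.finite(s) || s <= 0)
      stop("column '", cn, "' has zero variance and cannot be standardized")
    out[[cn]] <- (v - m) / s
    means <- c(means, m); sds <- c(sds, s)
  }
  params <- data.frame(column = columns, mean = means, sd = sds,
                       stringsAsFactors = FALSE)
  attr(out, "scale") <- "standardized"
  list(data = out, params = params)
}

#' Invert a standardization
#'
#' @param table a standardized trip table.
#' @param params the `params` data.frame returned by [standardize()].
#' @return the table on its original scale.
#' @export
unstandardize <- function(table, params) {
  out <- table
  for (i in seq_len(nrow(params))) {
    cn <- params$column[i]
    if (!cn %in% names(out)) stop("column '", cn, "' not present")
    out[[cn]] <- out[[cn]] * params$sd[i] + params$mean[i]
  }
  attr(out, "scale") <- "raw"
  out
}

#' Drop trips with missing analysis variables
#'
#' Complete-case filter: removes every row with at least one `NA` among
#' the analysis columns and reports how many were dropped.
#'
#' @param table a data.frame of trips.
#' @param columns columns to require complete; defaults to all.
#' @param quiet suppress the message.
#' @return the filtered data.frame.
#' @export
drop_incomplete <- function(table, columns = names(table), quiet = FALSE) {
  stopifnot(is.data.frame(table))
  keep <- stats::complete.cases(table[, columns, drop = FALSE])
  dropped <- sum(!keep)
  if (!quiet && dropped > 0)
    message("drop_incomplete: removed ", dropped, " of ", nrow(table),
            " trips with missing values")
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read standardization parameters as a JSON sidecar
#'
#' @param params the `params` data.frame from [standardize()].
#' @param path file path.
#' @export
write_standardization <- function(params, path) {
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_standardization
#' @export
read_standardization <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
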