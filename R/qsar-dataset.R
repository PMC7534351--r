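#' Assemble a fitting-ready QSAR dataset
#'
#' Extracts one response column and a descriptor matrix from a
#' [descriptor_table], dropping compounds whose response is missing. Small-n
#' QSAR fits need spare degrees of freedom for the standard error of
#' estimate and the F-statistic, so construction refuses datasets with
#' n < p + 2.
#'
#' @param table A [descriptor_table].
#' @param response Name of the response column to model.
#' @param descriptors Optional character vector selecting (and ordering) the
#'   descriptor columns; all descriptors in table order when omitted.
#'
#' @return An object of class `qsar_dataset`: a list with elements `ids`,
#'   `y` (response vector), `X` (n x p numeric matrix), `descriptor_names`,
#'   `response`, `n`, `p`. `as_tibble()` turns it back into a tidy table.
#' @examples
#' tbl <- raf_descriptor_table()
#' build_qsar_dataset(tbl, "pIC50_RAF1") # 9 compounds, 6 descriptors
#' @export
build_qsar_dataset <- function(table, response, descriptors = NULL) {
  roles <- table_roles(table)
  if (!response %in% roles$responses) {
    abort(sprintf("Response column '%s' not found (available: %s).",
                  response, paste(roles$responses, collapse = ", ")))
  }
  if (is.null(descriptors)) {
    descriptors <- roles$descriptors
  } else {
    unknown <- setdiff(descriptors, roles$descriptors)
    if (length(unknown)) {
      abort(sprintf("Unknown descriptor(s): %s.", paste(unknown, collapse = ", ")))
    }
  }
  keep <- !is.na(table[[response]])
  n <- sum(keep)
  p <- length(descriptors)
  if (n < p + 2) {
    abort(sprintf(
      "insufficient degrees of freedom: n = %d compounds with '%s' but p = %d descriptors (need n >= p + 2).",
      n, response, p
    ))
  }
  X <- as.matrix(as.data.frame(table)[keep, descriptors, drop = FALSE])
  storage.mode(X) <- "double"
  structure(
    list(
      ids = table[[roles$id]][keep],
      y = as.numeric(table[[response]][keep]),
      X = X,
      descriptor_names = descriptors,
      response = response,
      n = n,
      p = p
    ),
    class = "qsar_dataset"
  )
}

#' Build a qsar_dataset directly from matrix-like pieces
#'
#' Lower-level constructor used by the synthetic-data generator and by
#' tests; performs the same completeness and degrees-of-freedom checks as
#' [build_qsar_dataset()].
#'
#' @param X Numeric matrix (or data frame) of descriptors with column names.
#' @param y Numeric response vector, length `nrow(X)`, no missing values.
#' @param ids Optional compound labels; defaults to `cpd_1..n`.
#' @param response Label for the response, used in printing and reports.
#' @return A `qsar_dataset`.
#' @export
qsar_dataset <- function(X, y, ids = NULL, response = "response") {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("D", seq_len(ncol(X)))
  if (length(y) != nrow(X)) abort("`y` must have one value per row of `X`.")
  if (anyNA(X) || anyNA(y)) abort("`X` and `y` must be complete (no missing values).")
  if (is.null(ids)) ids <- paste0("cpd_", seq_len(nrow(X)))
  n <- nrow(X); p <- ncol(X)
  if (n < p + 2) {
    abort(sprintf("insufficient degrees of freedom: n = %d, p = %d (need n >= p + 2).", n, p))
  }
  structure(
    list(ids = as.character(ids), y = as.numeric(y), X = X,
         descriptor_names = colnames(X), response = response, n = n, p = p),
    class = "qsar_dataset"
  )
}

#' @export
print.qsar_dataset <- function(x, ...) {
  cat(sprintf("<qsar_dataset> %s: n = %d compounds, p = %d descriptors (%s)\n",
              x$response, x$n, x$p, paste(x$descriptor_names, collapse = ", ")))
  invisible(x)
}

#' @export
as_tibble.qsar_dataset <- function(x, ...) {
  dplyr::bind_cols(
    tibble(compound = x$ids, !!x$response := x$y),
    as_tibble(as.data.frame(x$X))
  )
}

# Restrict a dataset to a descriptor subset (order as given).
subset_dataset <- function(dataset, descriptors) {
  unknown <- setdiff(descriptors, dataset$descriptor_names)
  if (length(unknown)) {
    abort(sprintf("Unknown descriptor(s): %s.", paste(unknown, collapse = ", ")))
  }
  dataset$X <- dataset$X[, descriptors, drop = FALSE]
  dataset$descriptor_names <- descriptors
  dataset$p <- length(descriptors)
  dataset
}
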