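#' Missing-response sentinels recognised on read
#'
#' Printed potency tables mark not-determined responses with a dash or "ND";
#' these strings (plus empty cells and "NA") parse as missing pIC50.
#' @keywords internal
MISSING_SENTINELS <- c("–", "-", "", "NA", "ND")

#' Construct a descriptor table
#'
#' A descriptor table is the raw per-compound input of a QSAR study: one
#' opaque compound identifier per row, one or more response columns in pIC50
#' units (missing entries allowed -- not every compound is assayed against
#' every target), and numeric molecular-descriptor columns with no missing
#' values. It is an ordinary tibble carrying a column-role attribute, so all
#' dplyr verbs apply; role-aware operations ([build_qsar_dataset()],
#' [check_potency_consistency()]) consult the roles.
#'
#' @param data A data frame. The first column (or `id_col`) holds compound
#'   identifiers; they must be unique.
#' @param response_cols Character vector naming the response (pIC50)
#'   columns. Every remaining non-id column is treated as a descriptor.
#' @param id_col Name of the identifier column. Defaults to the first
#'   column.
#'
#' @return A tibble of class `descriptor_table`.
#' @seealso [read_descriptor_table()] to build one from a CSV file.
#' @export
descriptor_table <- function(data, response_cols = character(), id_col = names(data)[1]) {
  stopifnot(is.data.frame(data))
  if (!id_col %in% names(data)) abort(sprintf("id column '%s' not found.", id_col))
  missing_resp <- setdiff(response_cols, names(data))
  if (length(missing_resp)) {
    abort(sprintf("Response column(s) not found: %s.", paste(missing_resp, collapse = ", ")))
  }
  ids <- as.character(data[[id_col]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(sprintf("Duplicate compound ids: %s.", paste(dup, collapse = ", ")))
  }
  descriptor_cols <- setdiff(names(data), c(id_col, response_cols))
  for (col in descriptor_cols) {
    v <- data[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))) & !is.na(v))
      abort(sprintf(
        "Descriptor column '%s' is not numeric (first offending row: %d).",
        col, if (length(bad)) bad[1] else 1L
      ))
    }
    if (anyNA(v)) {
      abort(sprintf(
        "Descriptor column '%s' has missing values (row %d); descriptors must be complete.",
        col, which(is.na(v))[1]
      ))
    }
  }
  for (col in response_cols) {
    if (!is.numeric(data[[col]])) {
      abort(sprintf("Response column '%s' must be numeric.", col))
    }
  }
  out <- as_tibble(data)
  out[[id_col]] <- ids
  attr(out, "qsar_roles") <- list(
    id = id_col, responses = response_cols, descriptors = descriptor_cols
  )
  class(out) <- c("descriptor_table", class(out))
  out
}

table_roles <- function(table) {
  roles <- attr(table, "qsar_roles")
  if (is.null(roles)) abort("Not a descriptor_table (missing column roles).")
  roles
}

#' @export
print.descriptor_table <- function(x, ...) {
  roles <- table_roles(x)
  cat(sprintf(
    "<descriptor_table> %d compounds, %d response(s) [%s], %d descriptors\n",
    nrow(x), length(roles$responses), paste(roles$responses, collapse = ", "),
    length(roles$descriptors)
  ))
  NextMethod()
}

#' Read a descriptor table from CSV
#'
#' Expects a UTF-8, comma-separated file with a mandatory header row, '.'
#' decimal mark, and the compound-identifier column first. Cells equal to
#' any of `na` (en-dash, hyphen, empty, "NA", "ND") in a response column
#' parse as missing; the same strings in a descriptor column are an error,
#' since descriptor values must be complete.
#'
#' @param path Path to the CSV file.
#' @param response_cols Character vector of response column names. Columns
#'   whose name starts with `"pIC50"` are used when omitted.
#' @param na Strings to interpret as missing.
#' @inheritParams descriptor_table
#'
#' @return A [descriptor_table].
#' @export
read_descriptor_table <- function(path, response_cols = NULL,
                                  na = MISSING_SENTINELS, id_col = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (file.size(path) == 0) abort(sprintf("no header: file '%s' is empty.", path))
  raw <- readr::read_csv(path, na = na, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  if (ncol(raw) < 2) abort("Descriptor table needs an id column plus data columns.")
  if (is.null(id_col)) id_col <- names(raw)[1]
  if (is.null(response_cols)) {
    response_cols <- grep("^pIC50", names(raw), value = TRUE)
  }
  for (col in setdiff(names(raw), id_col)) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad)) {
      abort(sprintf("Non-numeric value '%s' in column '%s', row %d.",
                    raw[[col]][bad[1]], col, bad[1]))
    }
    raw[[col]] <- v
  }
  descriptor_table(raw, response_cols = response_cols, id_col = id_col)
}

#' Write a descriptor table to CSV or JSON
#'
#' `write_descriptor_table()` emits the CSV dialect that
#' [read_descriptor_table()] reads (missing responses as "-"), so a
#' read-write-read round trip is lossless at printed precision.
#' `descriptor_table_json()` serialises the table with its column roles for
#' provenance tracking.
#'
#' @param table A [descriptor_table].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(table, path) {
  roles <- table_roles(table)
  out <- as.data.frame(table)
  for (col in roles$responses) {
    v <- out[[col]]
    out[[col]] <- ifelse(is.na(v), "-", format(v, trim = TRUE, scientific = FALSE))
  }
  readr::write_csv(out, path, na = "-", progress = FALSE)
  invisible(path)
}

#' @rdname write_descriptor_table
#' @export
descriptor_table_json <- function(table, path) {
  roles <- table_roles(table)
  payload <- list(
    roles = roles,
    compounds = table[[roles$id]],
    responses = as.list(table[roles$responses]),
    descriptors = as.list(table[roles$descriptors])
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Bundled imidazothiazole V600E-B-RAF / RAF1 study data
#'
#' Accessors for the package's worked dataset: a series of imidazothiazole
#' kinase inhibitors assayed against the oncogenic V600E mutant of B-RAF and
#' against RAF1, with software-computed molecular descriptors (INTEGY
#' moments IW1/IW2, flexibility FLEX, polar surface area PSA, the
#' acceptor-donor-donor pharmacophore count ACDODO, and the hydrophobic
#' volume difference DD8) for the 22 compounds with measured V600E-B-RAF
#' pIC50, 9 of which also have RAF1 pIC50.
#'
#' @return
#' * `raf_descriptor_table()`: a [descriptor_table] (22 compounds, responses
#'   `pIC50_V600E` and `pIC50_RAF1`, 6 descriptors).
#' * `raf_kinase_potency()`: tibble of per-compound percent inhibition at
#'   1 uM and IC50s (column `ic50` in molar, converted from the nM values in
#'   the source file) against RAF1, V600E-B-RAF and (for compound 1zb) FLT3.
#' * `raf_kinase_panel()`: tibble of compound 1zb's mean percent inhibition
#'   at 1 uM across a 30-kinase panel.
#' * `raf_cell_viability()`: tibble of cell-line IC50s (column `ic50` in
#'   molar) for compound 1zb and sorafenib against four melanoma lines and
#'   normal skin epithelial cells.
#' @export
raf_descriptor_table <- function() {
  read_descriptor_table(qsarforge_extdata("imidazothiazole_descriptors.csv"))
}

#' @rdname raf_descriptor_table
#' @export
raf_kinase_potency <- function() {
  x <- readr::read_csv(qsarforge_extdata("kinase_potency.csv"),
                       na = MISSING_SENTINELS,
                       col_types = "ccddd", progress = FALSE, show_col_types = FALSE)
  dplyr::mutate(x, ic50 = .data$ic50_nM * 1e-9)
}

#' @rdname raf_descriptor_table
#' @export
raf_kinase_panel <- function() {
  readr::read_csv(qsarforge_extdata("kinase_panel.csv"), col_types = "cdd",
                  progress = FALSE, show_col_types = FALSE)
}

#' @rdname raf_descriptor_table
#' @export
raf_cell_viability <- function() {
  x <- readr::read_csv(qsarforge_extdata("cell_viability.csv"), col_types = "cccdd",
                       progress = FALSE, show_col_types = FALSE)
  dplyr::mutate(x, ic50 = .data$ic50_uM * 1e-6)
}

qsarforge_extdata <- function(file) {
  path <- system.file("extdata", file, package = "qsarforge")
  if (path == "") abort(sprintf("Bundled data file '%s' not found.", file))
  path
}
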