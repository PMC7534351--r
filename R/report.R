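#' Summarise a kinase selectivity panel
#'
#' Filters a single-dose percent-inhibition panel to the kinases at or
#' above a threshold. Percent inhibition may legitimately be slightly
#' negative (assay noise around zero) and is never clamped. The default
#' semantics are inclusive (>= threshold); `strict = TRUE` switches to
#' strictly-greater, the convention used when a screen advances compounds
#' showing "more than" a stated inhibition level.
#'
#' @param panel Data frame with columns `kinase` and `pct_inhibition`.
#' @param threshold Percent-inhibition cutoff, in \[-100, 110\].
#' @param strict Use `>` instead of `>=`.
#' @return A tibble of hits sorted by inhibition, descending.
#' @examples
#' panel_summary(raf_kinase_panel(), 50) # V600E-B-RAF and FLT3
#' @export
panel_summary <- function(panel, threshold = 50, strict = FALSE) {
  stopifnot(is.data.frame(panel),
            all(c("kinase", "pct_inhibition") %in% names(panel)))
  if (threshold < -100 || threshold > 110) {
    abort("`threshold` must lie in [-100, 110] percent.")
  }
  hits <- if (strict) {
    dplyr::filter(panel, .data$pct_inhibition > threshold)
  } else {
    dplyr::filter(panel, .data$pct_inhibition >= threshold)
  }
  dplyr::arrange(as_tibble(hits), dplyr::desc(.data$pct_inhibition))
}

#' Selectivity report for one compound
#'
#' Collates the selectivity narrative of a kinase inhibitor: fold-ratios of
#' every off-target kinase IC50 over the on-target IC50, and -- when cell
#' viability data are supplied -- the selectivity index of each tumour line
#' (normal-cell IC50 / tumour-cell IC50). Ratios are unrounded; round to 2
#' decimals for display.
#'
#' @param compound Compound identifier.
#' @param potency Tibble with columns `compound`, `kinase`, `ic50` (molar),
#'   e.g. [raf_kinase_potency()].
#' @param on_target Name of the on-target kinase.
#' @param cells Optional tibble with columns `cell_line`, `tissue`,
#'   `compound`, `ic50` (molar), e.g. [raf_cell_viability()]; rows with
#'   tissue `"normal skin"` (or matching `normal_tissue`) provide the
#'   normal-cell reference.
#' @param normal_tissue Tissue label identifying the normal cell line.
#' @return A list of class `qsar_selectivity`: `compound`, `on_target`
#'   (name + molar IC50), `kinases` (tibble with `fold_ratio`), `cells`
#'   (tibble with `selectivity_index`, or `NULL`).
#' @export
selectivity_report <- function(compound, potency, on_target = "V600E-B-RAF",
                               cells = NULL, normal_tissue = "normal skin") {
  pot <- dplyr::filter(potency, .data$compound == !!compound, !is.na(.data$ic50))
  on_row <- dplyr::filter(pot, .data$kinase == on_target)
  if (nrow(on_row) != 1) {
    abort(sprintf("Expected exactly one on-target IC50 for %s against %s.",
                  compound, on_target))
  }
  on_ic50 <- on_row$ic50
  off <- dplyr::filter(pot, .data$kinase != on_target)
  kinases <- dplyr::mutate(
    dplyr::select(off, "kinase", "ic50"),
    fold_ratio = selectivity_ratio(.data$ic50, on_ic50)
  )
  cell_tbl <- NULL
  if (!is.null(cells)) {
    cc <- dplyr::filter(cells, .data$compound == !!compound)
    normal <- dplyr::filter(cc, .data$tissue == normal_tissue)
    if (nrow(normal) != 1) {
      abort(sprintf("Expected exactly one '%s' IC50 for %s.", normal_tissue, compound))
    }
    tumour <- dplyr::filter(cc, .data$tissue != normal_tissue)
    cell_tbl <- dplyr::mutate(
      dplyr::select(tumour, "cell_line", "ic50"),
      selectivity_index = cell_selectivity_index(normal$ic50, .data$ic50)
    )
  }
  structure(
    list(compound = compound,
         on_target = list(name = on_target, ic50 = on_ic50),
         kinases = kinases, cells = cell_tbl),
    class = "qsar_selectivity"
  )
}

#' @export
print.qsar_selectivity <- function(x, ...) {
  cat(sprintf("<qsar_selectivity> %s vs %s (IC50 %.3g nM)\n",
              x$compound, x$on_target$name, x$on_target$ic50 * 1e9))
  for (i in seq_len(nrow(x$kinases))) {
    cat(sprintf("  %s: %.2f-fold\n", x$kinases$kinase[i], x$kinases$fold_ratio[i]))
  }
  if (!is.null(x$cells)) {
    for (i in seq_len(nrow(x$cells))) {
      cat(sprintf("  %s: selectivity index %.2f\n",
                  x$cells$cell_line[i], x$cells$selectivity_index[i]))
    }
  }
  invisible(x)
}

# MD5 sums of the bundled fixtures, recorded at packaging time so the
# reference analysis can refuse to run on altered inputs.
FIXTURE_MD5 <- c(
  cell_viability.csv = "626d1c9d69e1a96c7033dc372dab347a",
  imidazothiazole_descriptors.csv = "58b7647332bb21787e0818749a52b031",
  kinase_panel.csv = "f96f60026c4efa7d2f8d0daf48e7bcbd",
  kinase_potency.csv = "fb124c8b06e3e120fce63df6729c1e68"
)

check_fixtures <- function() {
  for (file in names(FIXTURE_MD5)) {
    sum <- unname(tools::md5sum(qsarforge_extdata(file)))
    if (!identical(sum, unname(FIXTURE_MD5[[file]]))) {
      abort(sprintf("Fixture checksum mismatch for '%s' (got %s).", file, sum))
    }
  }
  invisible(TRUE)
}

#' Run the full bundled kinase-inhibitor analysis
#'
#' End-to-end, deterministic reproduction of the bundled study's
#' descriptor-based QSAR analysis:
#' verifies the fixture checksums and the IC50/pIC50 transcription
#' consistency, refits the two published equations -- pIC50(RAF1) on
#' \{IW1, FLEX\} over the 9 compounds with RAF1 data, and pIC50(V600E-B-RAF)
#' on \{ACDODO, IW2, DD8, PSA\} over all 22 compounds -- runs leave-one-out
#' validation for both, and writes the report bundle: per-model JSON,
#' a statistics table, experimental-versus-predicted scatter data with 95%
#' confidence and prediction limits, the selectivity report for the lead
#' compound 1zb, and the kinase-panel hit list at the 50% threshold.
#'
#' @param out_dir Output directory (created if needed).
#' @param level Coverage probability for the scatter bands.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `models` (named list of `qsar_mlr`),
#'   `stats` (tibble), `selectivity` (`qsar_selectivity`), `panel_hits`
#'   (tibble) and `paths` (character vector of files written).
#' @export
run_reference_analysis <- function(out_dir, level = 0.95, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  say("Checking fixture checksums")
  check_fixtures()

  say("Loading bundled descriptor and potency tables")
  table <- raf_descriptor_table()
  potency <- raf_kinase_potency()
  panel <- raf_kinase_panel()
  cells <- raf_cell_viability()

  say("Cross-checking IC50/pIC50 transcription")
  bad <- check_potency_consistency(
    potency, table,
    map = c("RAF1" = "pIC50_RAF1", "V600E-B-RAF" = "pIC50_V600E")
  )
  if (nrow(bad)) {
    abort(sprintf("Potency transcription inconsistent for: %s.",
                  paste(bad$compound, collapse = ", ")))
  }

  dir.create(file.path(out_dir, "models"), recursive = TRUE, showWarnings = FALSE)
  specs <- list(
    raf1 = list(response = "pIC50_RAF1", descriptors = c("IW1", "FLEX")),
    v600e = list(response = "pIC50_V600E",
                 descriptors = c("ACDODO", "IW2", "DD8", "PSA"))
  )
  models <- list()
  paths <- character()
  stats_rows <- list()
  for (name in names(specs)) {
    sp <- specs[[name]]
    say("Fitting %s model: %s ~ {%s}", name, sp$response,
        paste(sp$descriptors, collapse = ", "))
    fit <- fit_mlr(table, sp$response, sp$descriptors)
    models[[name]] <- fit
    mp <- file.path(out_dir, "models", paste0(name, ".json"))
    write_model_json(fit, mp)
    band <- prediction_band(fit, level = level)
    scp <- file.path(out_dir, paste0("scatter_", name, ".csv"))
    readr::write_csv(band, scp, progress = FALSE)
    stats_rows[[name]] <- dplyr::bind_cols(model = name, glance(fit))
    paths <- c(paths, mp, scp)
  }
  stats <- dplyr::bind_rows(stats_rows)
  stats_path <- file.path(out_dir, "stats.csv")
  say("Writing model statistics table")
  readr::write_csv(stats, stats_path, progress = FALSE)

  say("Building selectivity report for compound 1zb")
  sel <- selectivity_report("1zb", potency, on_target = "V600E-B-RAF", cells = cells)
  sel_path <- file.path(out_dir, "selectivity_1zb.json")
  jsonlite::write_json(
    list(compound = sel$compound, on_target = sel$on_target,
         kinases = sel$kinases, cells = sel$cells),
    sel_path, auto_unbox = TRUE, digits = NA
  )

  say("Summarising kinase panel at the 50%% threshold")
  hits <- panel_summary(panel, threshold = 50)
  hits_path <- file.path(out_dir, "panel_hits.csv")
  readr::write_csv(hits, hits_path, progress = FALSE)

  invisible(list(
    models = models, stats = stats, selectivity = sel, panel_hits = hits,
    paths = c(paths, stats_path, sel_path, hits_path)
  ))
}
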