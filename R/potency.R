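#' Convert between IC50 and pIC50
#'
#' pIC50 is the negative base-10 logarithm of the half-maximal inhibitory
#' concentration expressed in molar units; larger values mean more potent
#' compounds. All package-internal concentrations are molar -- convert
#' nanomolar assay read-outs with `ic50 * 1e-9` before calling.
#'
#' @param ic50 Numeric vector of IC50 values in molar units. Must be
#'   strictly positive.
#' @param pic50 Numeric vector of pIC50 values (unitless).
#'
#' @return `ic50_to_pic50()` returns pIC50 values; `pic50_to_ic50()` returns
#'   molar concentrations. The two are mutually inverse to within 1e-12
#'   relative error.
#'
#' @examples
#' ic50_to_pic50(0.978e-9) # 9.010 at 3 decimals
#' pic50_to_ic50(9.010)    # ~0.977 nM
#' @export
ic50_to_pic50 <- function(ic50) {
  if (!is.numeric(ic50)) abort("`ic50` must be numeric.")
  if (any(!is.finite(ic50)) || any(ic50 <= 0)) {
    abort("`ic50` must be finite and strictly positive (molar concentration).")
  }
  -log10(ic50)
}

#' @rdname ic50_to_pic50
#' @export
pic50_to_ic50 <- function(pic50) {
  if (!is.numeric(pic50)) abort("`pic50` must be numeric.")
  if (any(!is.finite(pic50))) abort("`pic50` must be finite.")
  10^(-pic50)
}

#' Fold-selectivity between two inhibition targets
#'
#' The fold-selectivity of an inhibitor for its on-target over an off-target
#' is the ratio of off-target to on-target IC50; values above 1 indicate
#' preferential on-target action. For cell lines the same ratio of
#' normal-cell to tumour-cell IC50 is conventionally called the selectivity
#' index.
#'
#' Ratios are returned unrounded; display at 2 decimals is a formatting
#' choice left to the caller.
#'
#' @param off_target_ic50,on_target_ic50 IC50 values in molar units
#'   (strictly positive).
#' @param normal_ic50,tumour_ic50 IC50 values in molar units (strictly
#'   positive).
#'
#' @return A numeric vector of ratios.
#'
#' @examples
#' selectivity_ratio(838e-9, 0.978e-9) # ~856.85-fold selective
#' cell_selectivity_index(9.26e-6, 0.18e-6) # ~51.44
#' @export
selectivity_ratio <- function(off_target_ic50, on_target_ic50) {
  check_positive(off_target_ic50, "off_target_ic50")
  check_positive(on_target_ic50, "on_target_ic50")
  off_target_ic50 / on_target_ic50
}

#' @rdname selectivity_ratio
#' @export
cell_selectivity_index <- function(normal_ic50, tumour_ic50) {
  check_positive(normal_ic50, "normal_ic50")
  check_positive(tumour_ic50, "tumour_ic50")
  normal_ic50 / tumour_ic50
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("`%s` must be finite and strictly positive.", name))
  }
  invisible(x)
}

#' Cross-check printed IC50s against printed pIC50s
#'
#' Published potency tables often report raw IC50s in one table and pIC50
#' transforms in another; transcription errors between the two are a common
#' source of irreproducible QSAR fits. This check recomputes
#' \eqn{-\log_{10}(\mathrm{IC50})} for every compound shared between a
#' potency table and a descriptor table and flags any pair whose printed
#' pIC50 differs from the recomputed value by more than `tol` after rounding
#' to 3 decimals.
#'
#' @param potencies A data frame with columns `compound`, `ic50` (molar) and
#'   a grouping column named by `target_col` identifying which response each
#'   IC50 belongs to.
#' @param table A [descriptor_table] whose response columns hold pIC50s.
#' @param map Named character vector mapping values of `target_col` to
#'   response column names of `table`, e.g.
#'   `c("RAF1" = "pIC50_RAF1")`. Unmapped targets are ignored.
#' @param target_col Name of the grouping column in `potencies`.
#' @param tol Absolute tolerance on the 3-decimal comparison. Default 5e-4,
#'   i.e. agreement at the printed precision.
#'
#' @return A tibble of discrepancies (compound, target, ic50, printed and
#'   recomputed pIC50, absolute difference); zero rows means the two tables
#'   are mutually consistent.
#' @export
check_potency_consistency <- function(potencies, table, map,
                                      target_col = "kinase", tol = 5e-4) {
  stopifnot(is.data.frame(potencies), inherits(table, "descriptor_table"))
  if (is.null(names(map)) || any(names(map) == "")) {
    abort("`map` must be a named character vector: target -> response column.")
  }
  roles <- table_roles(table)
  id_col <- roles$id
  out <- purrr::map_dfr(names(map), function(target) {
    resp <- map[[target]]
    if (!resp %in% roles$responses) {
      abort(sprintf("Response column '%s' not found in descriptor table.", resp))
    }
    pot <- potencies[potencies[[target_col]] == target & !is.na(potencies$ic50), ,
                     drop = FALSE]
    printed <- table[[resp]][match(pot$compound, table[[id_col]])]
    keep <- !is.na(printed)
    recomputed <- round(ic50_to_pic50(pot$ic50[keep]), 3)
    tibble(
      compound = pot$compound[keep],
      target = target,
      ic50 = pot$ic50[keep],
      pic50_printed = printed[keep],
      pic50_recomputed = recomputed,
      abs_diff = abs(recomputed - printed[keep])
    )
  })
  dplyr::filter(out, .data$abs_diff > tol)
}
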