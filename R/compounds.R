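# Loading and validation of the packaged 46-compound structure/activity table
# (30 training compounds D1-D30, 16 external test compounds F1-F16) and the
# activity transform. IC50 values are in micromolar; pIC50 is defined on the
# micromolar scale because the test-set tables of the source study follow that
# convention. Reported pIC50 values are kept verbatim even where they disagree
# with -log10(IC50).

#' Convert an IC50 in micromolar to pIC50
#'
#' @param ic50_uM positive IC50 value(s) in micromolar.
#' @return `-log10(ic50_uM)`, dimensionless.
#' @examples
#' pic50_from_ic50(1)       # 0
#' pic50_from_ic50(16.16)   # -1.21
#' @export
pic50_from_ic50 <- function(ic50_uM) {
  if (!is.numeric(ic50_uM) || any(!is.finite(ic50_uM)) || any(ic50_uM <= 0))
    stop("ic50_uM must be positive and finite")
  -log10(ic50_uM)
}

#' Inverse of [pic50_from_ic50()]
#'
#' @param pic50 dimensionless activity.
#' @return IC50 in micromolar.
#' @export
ic50_from_pic50 <- function(pic50) {
  if (!is.numeric(pic50) || any(!is.finite(pic50)))
    stop("pic50 must be finite")
  10^(-pic50)
}

#' Load and validate a compound activity table
#'
#' With no argument the packaged 46-compound 3,5-diaryl-4,5-dihydropyrazole
#' table is loaded (SMILES encoded from the systematic names of the series and
#' cross-checked against the published characterization data, see
#' [validate_characterization()]). A user CSV must provide columns `id`,
#' `role`, `smiles`, `ic50_uM` (and optionally `pic50_reported`).
#'
#' @param source path to a CSV file, or `NULL` for the packaged table.
#' @return a `compound_table`: a data.frame with columns `id`, `role`
#'   (`train`/`test`), `smiles`, `ic50_uM`, `pic50_reported` and
#'   `pic50_computed` (always `-log10(ic50_uM)`), in input order.
#' @examples
#' tab <- load_activity_table()
#' subset(tab, id == "D5")$ic50_uM   # 0.09
#' @export
load_activity_table <- function(source = NULL) {
  packaged <- is.null(source)
  if (packaged)
    source <- system.file("extdata", "activity_table.csv", package = "comfar",
                          mustWork = TRUE)
  if (!file.exists(source)) stop("activity table not readable: ", source)
  tab <- utils::read.csv(source, stringsAsFactors = FALSE)
  need <- c("id", "role", "smiles", "ic50_uM")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("activity table missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(tab) == 0) stop("activity table validation error: no records")
  if (anyNA(tab$id) || any(tab$id == ""))
    stop("activity table validation error: missing id")
  dup <- unique(tab$id[duplicated(tab$id)])
  if (length(dup) > 0)
    stop("activity table validation error: duplicate id(s): ",
         paste(dup, collapse = ", "))
  if (!all(tab$role %in% c("train", "test")))
    stop("activity table validation error: role must be 'train' or 'test'")
  bad <- tab$id[!is.finite(tab$ic50_uM) | tab$ic50_uM <= 0]
  if (length(bad) > 0)
    stop("activity table validation error: non-positive IC50 for id(s): ",
         paste(bad, collapse = ", "))
  if (!"pic50_reported" %in% names(tab)) tab$pic50_reported <- NA_real_
  tab$pic50_computed <- pic50_from_ic50(tab$ic50_uM)
  if (packaged) {
    stopifnot(nrow(tab) == 46, sum(tab$role == "train") == 30,
              sum(tab$role == "test") == 16)
  }
  class(tab) <- c("compound_table", "data.frame")
  tab
}

#' Packaged characterization data for the compound series
#'
#' Molecular formula, printed ESI-MS `[M+H]+` m/z and calculated percent C/H/N
#' for each compound, transcribed verbatim from the published experimental
#' characterization.
#'
#' @return a data.frame with columns `id`, `formula`, `mz_printed`, `pct_C`,
#'   `pct_H`, `pct_N`.
#' @export
load_characterization <- function() {
  utils::read.csv(system.file("extdata", "characterization.csv",
                              package = "comfar", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Reported PLS cross-validation tables for the series
#'
#' The observed pIC50, the (undocumented) integer COMFA column and the
#' predicted pIC50/residual values as printed in the original study's PLS
#' tables, kept verbatim. Residuals follow observed - predicted for training
#' rows and predicted - observed for test rows in the source tables.
#'
#' @return a data.frame with columns `id`, `pic50`, `comfa`, `pre_pic50`,
#'   `residual`.
#' @export
load_reported_pls <- function() {
  utils::read.csv(system.file("extdata", "reported_pls.csv",
                              package = "comfar", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Cross-check packaged structures against characterization data
#'
#' For every compound the SMILES-derived molecular formula is compared with the
#' printed formula, the monoisotopic `[M+H]+` m/z with the printed MS value,
#' and the computed percent C/H/N with the printed calculated values.
#'
#' @param records a `compound_table` (default: the packaged table).
#' @param characterization characterization data (default: packaged).
#' @param mz_tol absolute m/z tolerance in Da.
#' @param pct_tol absolute tolerance on percent composition.
#' @return a data.frame with one row per compound: computed and printed values
#'   plus logical columns `formula_ok`, `mz_ok`, `pct_ok`.
#' @export
validate_characterization <- function(records = load_activity_table(),
                                      characterization = load_characterization(),
                                      mz_tol = 0.1, pct_tol = 0.01) {
  stopifnot(all(records$id %in% characterization$id))
  ch <- characterization[match(records$id, characterization$id), ]
  out <- data.frame(id = records$id, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(records))) {
    f <- formula_of(records$smiles[k])
    pc <- percent_composition(f)
    out$formula_computed[k] <- format(f)
    out$formula_printed[k] <- ch$formula[k]
    out$formula_ok[k] <- format(f) == format(parse_formula(ch$formula[k]))
    out$mz_computed[k] <- protonated_monoisotopic_mz(f)
    out$mz_printed[k] <- ch$mz_printed[k]
    out$mz_ok[k] <- abs(out$mz_computed[k] - ch$mz_printed[k]) <= mz_tol
    out$pct_C[k] <- pc[["C"]]; out$pct_H[k] <- pc[["H"]]; out$pct_N[k] <- pc[["N"]]
    out$pct_ok[k] <- abs(pc[["C"]] - ch$pct_C[k]) <= pct_tol &&
      abs(pc[["H"]] - ch$pct_H[k]) <= pct_tol &&
      abs(pc[["N"]] - ch$pct_N[k]) <= pct_tol
  }
  out
}
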