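# End-to-end CoMFA run on a compound table: embed, align onto the reference
# compound, build the lattice over the whole series (training + external set,
# so every molecule lies inside the hull), compute/filter/scale the training
# field table, fit the PLS model, cross-validate, predict the external set and
# derive contour thresholds. Identical configuration and seed give bit
# identical outputs.

#' Run the full CoMFA pipeline
#'
#' @param records a `compound_table` (default: the packaged 46-compound
#'   series).
#' @param seed embedding seed (every source of randomness in the run).
#' @param n_components PLS latent variables (default 6, the component count of
#'   the reproduced study).
#' @param spacing,margin lattice geometry in Angstrom (defaults 2.0 / 4.0).
#' @param cutoff field truncation in kcal/mol (default 30).
#' @param min_sigma column filter threshold in kcal/mol (default 2.0).
#' @param template_id alignment reference compound (default `"D5"`).
#' @param levels contour percent levels `c(favored, disfavored)`.
#' @param y_source `"reported"` trains on the transcribed pIC50 values (the
#'   response the original analysis used), `"computed"` on `-log10(IC50 uM)`.
#' @param ss_total q2 total-sum-of-squares convention, see
#'   [loo_cross_validate()].
#' @return a `comfa_result` list with elements `records`, `aligned`, `grid`,
#'   `table` (filtered+scaled training `field_table`), `model`, `stats`,
#'   `cv`, `contributions`, `train_predictions`, `test_predictions`,
#'   `external_stats` (when test compounds exist), `contours`, `config`.
#' @export
run_comfa <- function(records = load_activity_table(), seed = 42L,
                      n_components = 6L, spacing = 2.0, margin = 4.0,
                      cutoff = 30, min_sigma = 2.0, template_id = "D5",
                      levels = c(80, 20),
                      y_source = c("reported", "computed"),
                      ss_total = "fold") {
  y_source <- match.arg(y_source)
  y_all <- if (y_source == "reported" && !all(is.na(records$pic50_reported)))
    records$pic50_reported else records$pic50_computed
  names(y_all) <- records$id

  mols <- embed_series(records, seed)
  aligned <- align_series(mols, template_id = template_id)
  grid <- build_grid(aligned, spacing = spacing, margin = margin)

  train_ids <- records$id[records$role == "train"]
  test_ids <- records$id[records$role == "test"]
  table <- compute_field_table(aligned[train_ids], grid, cutoff = cutoff)
  table_raw <- table
  table <- scale_comfa_std(filter_columns(table, min_sigma))

  y <- unname(y_all[train_ids])
  model <- fit_pls(scaled_matrix(table), y, n_components)
  stats <- conventional_stats(model, scaled_matrix(table), y)
  cv <- loo_cross_validate(table_raw, y, n_components, ss_total = ss_total,
                           min_sigma = min_sigma)
  contributions <- field_contributions(model, table)
  train_pred <- predict_records(model, table, observed = y_all[train_ids])
  test_pred <- NULL; ext <- NULL
  if (length(test_ids) > 0) {
    test_pred <- predict_records(model, table, aligned[test_ids],
                                 observed = y_all[test_ids])
    if (sum(is.finite(test_pred$observed)) >= 3)
      ext <- external_validation_stats(test_pred, n_components)
  }
  contours <- contour_thresholds(model, table, levels)
  structure(list(
    records = records, aligned = aligned, grid = grid, table = table,
    model = model, stats = stats, cv = cv, contributions = contributions,
    train_predictions = train_pred, test_predictions = test_pred,
    external_stats = ext, contours = contours,
    config = list(seed = as.integer(seed), n_components = n_components,
                  spacing = spacing, margin = margin, cutoff = cutoff,
                  min_sigma = min_sigma, template_id = template_id,
                  levels = levels, y_source = y_source, ss_total = ss_total)
  ), class = "comfa_result")
}

#' @export
print.comfa_result <- function(x, ...) {
  cat(sprintf("<comfa_result> n = %d train, %d components\n",
              x$stats$n, x$stats$n_components))
  cat(sprintf("  r2 = %.3f, SEE = %.3f, F(%d, %d) = %.3f\n", x$stats$r2,
              x$stats$see, x$stats$df[1], x$stats$df[2], x$stats$f_value))
  cat(sprintf("  LOO: q2 = %.3f, PRESS = %.3f, SDEP = %.3f\n",
              x$cv$q2, x$cv$press, x$cv$sdep))
  cat(sprintf("  contributions: steric %.3f / electrostatic %.3f\n",
              x$contributions$steric_fraction,
              x$contributions$electrostatic_fraction))
  if (!is.null(x$external_stats))
    cat(sprintf("  external set: r2 = %.3f, SEE = %.3f (n = %d)\n",
                x$external_stats$r2, x$external_stats$see, x$external_stats$n))
  invisible(x)
}

#' Model summary of a pipeline run as a plain list
#'
#' @param result a `comfa_result`.
#' @return list mirroring the report JSON: n, components, r2, see, f_value,
#'   df, q2, press, sdep, contribution fractions, config and `per_compound`
#'   records (id, observed, fitted, loo_predicted, residual).
#' @export
model_summary <- function(result) {
  stopifnot(inherits(result, "comfa_result"))
  tp <- result$train_predictions
  cvp <- result$cv$predictions
  list(
    n = result$stats$n,
    components = result$stats$n_components,
    r2 = result$stats$r2,
    see = result$stats$see,
    f_value = result$stats$f_value,
    df = result$stats$df,
    q2 = result$cv$q2,
    press = result$cv$press,
    sdep = result$cv$sdep,
    steric_fraction = result$contributions$steric_fraction,
    electrostatic_fraction = result$contributions$electrostatic_fraction,
    external_r2 = if (!is.null(result$external_stats)) result$external_stats$r2,
    external_see = if (!is.null(result$external_stats)) result$external_stats$see,
    config = result$config,
    per_compound = lapply(seq_len(nrow(tp)), function(k) list(
      id = tp$id[k], observed = tp$observed[k], fitted = tp$predicted[k],
      loo_predicted = cvp$predicted[match(tp$id[k], cvp$id)],
      residual = tp$residual[k]
    ))
  )
}

#' Write the report bundle of a pipeline run
#'
#' Writes `report.json` (full model summary, config and seeds),
#' `training_predictions.csv`, `test_predictions.csv`,
#' `contours_steric.cube` and `contours_electrostatic.cube` (coef*sd values,
#' zero at masked lattice points) plus `alignment.sdf` with the aligned,
#' charged structures. Re-running with identical config and seed reproduces
#' `report.json` byte for byte.
#'
#' @param result a complete `comfa_result`.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  stopifnot(inherits(result, "comfa_result"))
  need <- c("model", "stats", "cv", "contributions", "train_predictions",
            "contours", "grid", "table")
  missing <- need[vapply(need, function(f) is.null(result[[f]]), logical(1))]
  if (length(missing) > 0)
    stop("incomplete pipeline result; missing stage output(s): ",
         paste(missing, collapse = ", "))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(model_summary(result), file.path(path, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  utils::write.csv(result$train_predictions,
                   file.path(path, "training_predictions.csv"), row.names = FALSE)
  if (!is.null(result$test_predictions))
    utils::write.csv(result$test_predictions,
                     file.path(path, "test_predictions.csv"), row.names = FALSE)
  map <- result$contours$map
  for (f in c("steric", "electrostatic")) {
    vals <- rep(0, n_grid_points(result$grid))
    sel <- map$field == f
    vals[map$point[sel]] <- map$value[sel]
    export_grid(vals, result$grid, "cube",
                file.path(path, paste0("contours_", f, ".cube")))
  }
  write_sdf(result$aligned, file.path(path, "alignment.sdf"))
  utils::write.csv(attr(result$aligned, "alignment_report"),
                   file.path(path, "alignment_report.csv"), row.names = FALSE)
  invisible(path)
}
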