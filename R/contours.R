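# External prediction, validation statistics, contour thresholds and grid /
# report export. The residual sign convention is observed - predicted
# everywhere in this package (the source study's test-set table uses the
# opposite sign; comparisons against that table must flip accordingly).

#' Predict compounds through a fitted field model
#'
#' @param model a `pls_model` fitted on `scaled_matrix(table)`.
#' @param table the training `field_table` (provides layout, mask, scaling).
#' @param mols list of aligned `molecule3d` to predict (their field rows are
#'   computed on the training grid), or `NULL` to predict the training rows.
#' @param observed optional named (by id) or positional vector of observed
#'   pIC50 values.
#' @return data.frame of prediction records: `id`, `observed`, `predicted`,
#'   `residual` (= observed - predicted; `NA` when unobserved).
#' @export
predict_records <- function(model, table, mols = NULL, observed = NULL) {
  stopifnot(inherits(model, "pls_model"), inherits(table, "field_table"))
  if (is.null(mols)) {
    X <- scaled_matrix(table)
    ids <- table$ids
  } else {
    X <- field_rows_for(table, mols)
    ids <- vapply(mols, function(m) m$id, character(1))
  }
  pred <- predict(model, X)
  obs <- rep(NA_real_, length(ids))
  if (!is.null(observed)) {
    obs <- if (!is.null(names(observed))) unname(observed[ids]) else observed
  }
  data.frame(id = ids, observed = obs, predicted = pred,
             residual = obs - pred, stringsAsFactors = FALSE)
}

#' External validation statistics
#'
#' `r2` is the squared Pearson correlation of observed vs predicted values;
#' `see` follows the conventional formula `sqrt(RSS/(n - c - 1))` with the
#' model's component count `c`.
#'
#' @param predictions data.frame of prediction records with `observed` and
#'   `predicted` columns (>= 3 observed rows).
#' @param n_components component count of the generating model.
#' @return list with `r2`, `see`, `n`.
#' @export
external_validation_stats <- function(predictions, n_components) {
  ok <- is.finite(predictions$observed) & is.finite(predictions$predicted)
  obs <- predictions$observed[ok]; prd <- predictions$predicted[ok]
  n <- length(obs)
  if (n < 3) stop("need at least 3 observed records")
  if (stats::var(obs) == 0) stop("zero variance in observed values")
  if (stats::var(prd) == 0) stop("undefined correlation: predictions are constant")
  rss <- sum((obs - prd)^2)
  list(r2 = stats::cor(obs, prd)^2,
       see = sqrt(rss / (n - n_components - 1)),
       n = n)
}

# Nearest-rank percentiles without interpolation, with the two tails treated
# symmetrically: the favored (upper) threshold counts ranks from below,
# v[ceiling(level/100 * n)], and the disfavored (lower) threshold is its
# mirror image, v[n + 1 - ceiling((100 - level)/100 * n)], so a sign-symmetric
# value distribution gives thresholds symmetric about zero.
.rank_upper <- function(values, level) {
  v <- sort(values)
  v[max(1L, ceiling(level / 100 * length(v)))]
}

.rank_lower <- function(values, level) {
  v <- sort(values)
  n <- length(v)
  v[min(n, n + 1L - ceiling((100 - level) / 100 * n))]
}

#' Contour threshold levels from the coefficient x sd map
#'
#' Per field, the favored threshold is the value at the `favored` percentile
#' of the per-point coef*sd distribution and the disfavored threshold the
#' value at the `disfavored` percentile, both by the nearest-rank rule (no
#' interpolation; the lower tail uses the mirrored rank so symmetric
#' distributions give symmetric thresholds). Points at or above the
#' favored threshold form the favored set (green for steric, blue for
#' electrostatic); points at or below the disfavored threshold the disfavored
#' set (yellow / red).
#'
#' @param model a `pls_model` fitted on `scaled_matrix(table)`.
#' @param table the training `field_table`.
#' @param levels numeric length-2 `c(favored, disfavored)` percent levels,
#'   default `c(80, 20)` (the alternative 70/30 convention is also common).
#' @return a `contour_spec`: per field a list with `favored_level`,
#'   `disfavored_level`, `favored_threshold`, `disfavored_threshold`,
#'   `favored_points`, `disfavored_points` (1-based lattice point indices) and
#'   the underlying `map` (from [coef_sd_map()]).
#' @export
contour_thresholds <- function(model, table, levels = c(80, 20)) {
  favored <- levels[1]; disfavored <- levels[2]
  if (!(disfavored > 0 && favored < 100 && disfavored < favored))
    stop("contour levels must satisfy 0 < disfavored < favored < 100")
  map <- coef_sd_map(model, table)
  out <- list(levels = c(favored = favored, disfavored = disfavored), map = map)
  for (f in c("steric", "electrostatic")) {
    v <- map$value[map$field == f]
    p <- map$point[map$field == f]
    if (length(v) == 0) next
    if (diff(range(v)) == 0)
      stop("degenerate contour input: all ", f, " values identical")
    fav <- .rank_upper(v, favored)
    dis <- .rank_lower(v, disfavored)
    out[[f]] <- list(favored_level = favored, disfavored_level = disfavored,
                     favored_threshold = fav, disfavored_threshold = dis,
                     favored_points = sort(p[v >= fav]),
                     disfavored_points = sort(p[v <= dis]))
  }
  structure(out, class = "contour_spec")
}

#' Export scalar lattice values as a Gaussian cube or OpenDX file
#'
#' Values must be in the package's raster order (k fastest), one per lattice
#' point. Cube headers follow the Gaussian convention (lengths in Bohr,
#' positive atom count); values are written at full precision so that
#' [read_grid()] round-trips them bit-identically.
#'
#' @param values numeric vector, one value per grid point.
#' @param grid a `grid_spec`.
#' @param format `"cube"` or `"dx"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_grid <- function(values, grid, format = c("cube", "dx"), path) {
  format <- match.arg(format)
  stopifnot(inherits(grid, "grid_spec"))
  if (length(values) != n_grid_points(grid))
    stop("value count ", length(values), " does not match grid point count ",
         n_grid_points(grid))
  bohr <- 1 / 0.529177210903
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "cube") {
    writeLines(c("comfar field grid", "scalar values, raster order (k fastest)"), con)
    writeLines(sprintf("%5d %.10f %.10f %.10f", 1L,
                       grid$origin[1] * bohr, grid$origin[2] * bohr,
                       grid$origin[3] * bohr), con)
    writeLines(sprintf("%5d %.10f %.10f %.10f", grid$counts[1],
                       grid$spacing * bohr, 0, 0), con)
    writeLines(sprintf("%5d %.10f %.10f %.10f", grid$counts[2],
                       0, grid$spacing * bohr, 0), con)
    writeLines(sprintf("%5d %.10f %.10f %.10f", grid$counts[3],
                       0, 0, grid$spacing * bohr), con)
    # single dummy atom so that viewers accept the file
    writeLines(sprintf("%5d %.6f %.10f %.10f %.10f", 6L, 0, 0, 0, 0), con)
    chunks <- split(values, ceiling(seq_along(values) / 6))
    writeLines(vapply(chunks, function(v)
      paste(sprintf("%.17g", v), collapse = " "), character(1)), con)
  } else {
    writeLines(sprintf("object 1 class gridpositions counts %d %d %d",
                       grid$counts[1], grid$counts[2], grid$counts[3]), con)
    writeLines(sprintf("origin %.10f %.10f %.10f", grid$origin[1],
                       grid$origin[2], grid$origin[3]), con)
    writeLines(sprintf("delta %.10f 0 0\ndelta 0 %.10f 0\ndelta 0 0 %.10f",
                       grid$spacing, grid$spacing, grid$spacing), con)
    writeLines(sprintf("object 2 class gridconnections counts %d %d %d",
                       grid$counts[1], grid$counts[2], grid$counts[3]), con)
    writeLines(sprintf("object 3 class array type double rank 0 items %d data follows",
                       length(values)), con)
    chunks <- split(values, ceiling(seq_along(values) / 3))
    writeLines(vapply(chunks, function(v)
      paste(sprintf("%.17g", v), collapse = " "), character(1)), con)
    writeLines('attribute "dep" string "positions"', con)
  }
  invisible(path)
}

#' Read back a grid file written by [export_grid()]
#'
#' @param path file path.
#' @param format `"cube"` or `"dx"`.
#' @return list with `values` and `grid` (a `grid_spec`).
#' @export
read_grid <- function(path, format = c("cube", "dx")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  bohr <- 1 / 0.529177210903
  num <- function(s) as.numeric(strsplit(trimws(s), "[[:space:]]+")[[1]])
  if (format == "cube") {
    h3 <- num(lines[3]); hx <- num(lines[4]); hy <- num(lines[5]); hz <- num(lines[6])
    natoms <- h3[1]
    counts <- c(hx[1], hy[1], hz[1])
    grid <- grid_spec(origin = h3[2:4] / bohr, spacing = hx[2] / bohr,
                      counts = counts)
    vals <- unlist(lapply(lines[(7 + natoms):length(lines)], num))
  } else {
    counts <- num(sub("object 1 class gridpositions counts", "", lines[1]))
    origin <- num(sub("origin", "", lines[2]))
    spacing <- num(sub("delta", "", lines[3]))[1]
    grid <- grid_spec(origin, spacing, counts)
    first <- grep("data follows$", lines) + 1
    last <- grep('^attribute', lines) - 1
    vals <- unlist(lapply(lines[first:last], num))
  }
  list(values = vals[seq_len(n_grid_points(grid))], grid = grid)
}
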