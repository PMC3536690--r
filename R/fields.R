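# CoMFA probe fields. At every lattice point the probe (an sp3 carbon with
# +1.0 e charge and a 1.52 Angstrom van der Waals radius) feels
#
#   steric        E = sum_atoms eps_ij [ (R_ij/r)^12 - 2 (R_ij/r)^6 ],
#                 R_ij = r_atom + r_probe, eps_ij = sqrt(eps_atom eps_probe),
#                 truncated at +cutoff (default +30 kcal/mol);
#   electrostatic E = sum_atoms K q_atom q_probe / r^2,
#                 K = 332.0 kcal A / (mol e^2); the distance-dependent
#                 dielectric (epsilon = r) contributes the second power of r;
#                 clipped to [-cutoff, +cutoff].
#
# Electrostatic values at sterically excluded points (steric at the truncation
# value) are replaced by the column mean over non-excluded compounds (the
# classic CoMFA convention; configurable off).

.COULOMB_K <- 332.0

#' Probe atom specification
#'
#' @param charge probe charge in e (default +1.0).
#' @param radius probe van der Waals radius in Angstrom (default 1.52).
#' @param epsilon probe well depth in kcal/mol (default: the sp3-carbon value
#'   of the embedded force-field table, 0.107).
#' @return an object of class `probe_spec`.
#' @export
probe_spec <- function(charge = 1.0, radius = 1.52, epsilon = 0.107) {
  stopifnot(radius > 0, epsilon > 0)
  structure(list(charge = charge, radius = radius, epsilon = epsilon),
            class = "probe_spec")
}

.atom_point_dist <- function(mol, points) {
  xyz <- coords(mol)
  d2 <- outer(rowSums(xyz^2), rowSums(points^2), "+") - 2 * xyz %*% t(points)
  sqrt(pmax(d2, 0))
}

#' Steric (Lennard-Jones) probe energy at lattice points
#'
#' @param point one point (length 3) or an n x 3 matrix of points (Angstrom).
#' @param mol a `molecule3d` with van der Waals parameters.
#' @param probe a [probe_spec()].
#' @param cutoff truncation value in kcal/mol.
#' @return energy in kcal/mol per point, truncated at `+cutoff` (a probe
#'   coincident with an atom returns exactly `+cutoff`).
#' @export
steric_energy_at <- function(point, mol, probe = probe_spec(), cutoff = 30) {
  points <- if (is.null(dim(point))) matrix(point, ncol = 3) else as.matrix(point)
  D <- .atom_point_dist(mol, points)
  R <- mol$atoms$radius + probe$radius
  eps <- sqrt(mol$atoms$epsilon * probe$epsilon)
  x6 <- (R / pmax(D, 1e-12))^6
  e <- colSums(eps * (x6^2 - 2 * x6))
  pmin(e, cutoff)
}

#' Electrostatic (Coulomb, distance-dependent dielectric) probe energy
#'
#' @inheritParams steric_energy_at
#' @return energy in kcal/mol per point, clipped to `[-cutoff, +cutoff]`.
#' @export
electrostatic_energy_at <- function(point, mol, probe = probe_spec(), cutoff = 30) {
  points <- if (is.null(dim(point))) matrix(point, ncol = 3) else as.matrix(point)
  D <- .atom_point_dist(mol, points)
  e <- .COULOMB_K * probe$charge * colSums(mol$atoms$charge / pmax(D, 1e-12)^2)
  pmin(pmax(e, -cutoff), cutoff)
}

#' Compute the compound x lattice field table
#'
#' One row per compound; columns are the full steric block followed by the
#' full electrostatic block, each in (i,j,k) raster order (k fastest). This
#' column order is normative for all file outputs.
#'
#' @param aligned list of aligned `molecule3d` objects.
#' @param grid a `grid_spec` built from (a superset of) this aligned set.
#' @param probe a [probe_spec()].
#' @param cutoff truncation/clipping value in kcal/mol (default 30).
#' @param exclude_electrostatics replace electrostatic values at sterically
#'   excluded points (steric at truncation) by the column mean over
#'   non-excluded compounds (default `TRUE`).
#' @return a `field_table`: list with the raw energy matrix `X` (rows named by
#'   compound id), `field` (`"steric"`/`"electrostatic"` per column), `point`
#'   (1-based raster point index per column), `mask` (all `TRUE` initially),
#'   `grid`, `probe`, `cutoff`, `scaling` (`NULL` until
#'   [scale_comfa_std()]).
#' @export
compute_field_table <- function(aligned, grid, probe = probe_spec(), cutoff = 30,
                                exclude_electrostatics = TRUE,
                                exclude_fill = NULL) {
  if (inherits(aligned, "molecule3d")) aligned <- list(aligned)
  stopifnot(inherits(grid, "grid_spec"), length(aligned) > 0)
  pts <- grid_points(grid)
  hull_lo <- grid$origin
  hull_hi <- grid$origin + (grid$counts - 1) * grid$spacing
  ids <- vapply(aligned, function(m) m$id, character(1))
  for (m in aligned) {
    xyz <- coords(m)
    if (any(sweep(xyz, 2, hull_lo) < -1e-9) || any(sweep(xyz, 2, hull_hi) > 1e-9))
      stop("atoms of compound ", m$id, " lie outside the grid hull")
  }
  np <- nrow(pts)
  S <- t(vapply(aligned, function(m)
    steric_energy_at(pts, m, probe, cutoff), numeric(np)))
  E <- t(vapply(aligned, function(m)
    electrostatic_energy_at(pts, m, probe, cutoff), numeric(np)))
  efill <- rep(0, np)
  if (exclude_electrostatics) {
    excl <- S >= cutoff - 1e-12
    for (p in seq_len(np)) {
      ex <- excl[, p]
      if (!all(ex)) efill[p] <- mean(E[!ex, p])
      if (any(ex))
        E[ex, p] <- if (is.null(exclude_fill)) efill[p] else exclude_fill[p]
    }
    if (!is.null(exclude_fill)) efill <- exclude_fill
  }
  X <- cbind(S, E)
  rownames(X) <- ids
  structure(list(
    X = X, ids = ids,
    field = rep(c("steric", "electrostatic"), each = np),
    point = rep(seq_len(np), 2),
    mask = rep(TRUE, 2 * np),
    grid = grid, probe = probe, cutoff = cutoff, scaling = NULL,
    efill = efill, exclude_electrostatics = exclude_electrostatics
  ), class = "field_table")
}

#' @export
print.field_table <- function(x, ...) {
  cat(sprintf("<field_table> %d compounds x %d columns (%d lattice points x 2 fields), %d unmasked%s\n",
              nrow(x$X), ncol(x$X), n_grid_points(x$grid), sum(x$mask),
              if (is.null(x$scaling)) "" else ", scaled"))
  invisible(x)
}

#' Drop low-variance columns (minimum-sigma filtering)
#'
#' Columns whose standard deviation (over compounds, n-1 denominator) is below
#' `min_sigma` are masked out; the raw data are retained so the mask can be
#' recomputed.
#'
#' @param table a `field_table`.
#' @param min_sigma threshold in kcal/mol (default 2.0, the customary CoMFA
#'   minimum-sigma).
#' @return the table with its `mask` updated.
#' @export
filter_columns <- function(table, min_sigma = 2.0) {
  stopifnot(inherits(table, "field_table"))
  sds <- apply(table$X, 2, stats::sd)
  mask <- sds >= min_sigma
  if (!any(mask))
    stop("no variance above threshold: all columns masked at min_sigma = ",
         min_sigma)
  table$mask <- mask
  table
}

#' CoMFA-standard block scaling
#'
#' Unmasked columns are mean-centered and each field block is divided by the
#' square root of its total column variance, so both blocks end up with equal
#' (unit) total variance. Parameters are stored for the inverse transform.
#'
#' @param table a filtered `field_table`.
#' @return the table with `scaling` set; `scaled_matrix()` returns the
#'   centered/scaled unmasked matrix.
#' @export
scale_comfa_std <- function(table) {
  stopifnot(inherits(table, "field_table"))
  center <- colMeans(table$X)
  vars <- apply(table$X, 2, stats::var)
  block_scale <- c(steric = NA_real_, electrostatic = NA_real_)
  for (f in c("steric", "electrostatic")) {
    sel <- table$mask & table$field == f
    if (!any(sel)) next
    tv <- sum(vars[sel])
    if (tv <= 0) stop("zero-variance ", f, " block cannot be scaled")
    block_scale[f] <- sqrt(tv)
  }
  table$scaling <- list(center = center, block_scale = block_scale)
  table
}

#' Centered/scaled descriptor matrix of the unmasked columns
#'
#' @param table a `field_table` after [scale_comfa_std()] (a table without
#'   scaling yields the raw unmasked matrix).
#' @param rows optional row (compound id or index) subset.
#' @return numeric matrix; column names encode `field:point`.
#' @export
scaled_matrix <- function(table, rows = NULL) {
  stopifnot(inherits(table, "field_table"))
  X <- table$X
  if (!is.null(table$scaling)) {
    X <- sweep(X, 2, table$scaling$center)
    for (f in names(table$scaling$block_scale)) {
      s <- table$scaling$block_scale[f]
      if (!is.na(s)) X[, table$field == f] <- X[, table$field == f] / s
    }
  }
  X <- X[, table$mask, drop = FALSE]
  colnames(X) <- paste0(table$field[table$mask], ":", table$point[table$mask])
  if (!is.null(rows)) X <- X[rows, , drop = FALSE]
  X
}

#' Invert the CoMFA-standard scaling
#'
#' @param table a scaled `field_table`.
#' @param X a scaled matrix over the unmasked columns (default: the table's
#'   own scaled matrix).
#' @return matrix on the raw energy scale (unmasked columns).
#' @export
unscale_matrix <- function(table, X = scaled_matrix(table)) {
  stopifnot(inherits(table, "field_table"), !is.null(table$scaling))
  fld <- table$field[table$mask]
  for (f in names(table$scaling$block_scale)) {
    s <- table$scaling$block_scale[f]
    if (!is.na(s)) X[, fld == f] <- X[, fld == f] * s
  }
  sweep(X, 2, table$scaling$center[table$mask], "+")
}

# Project new molecules onto an existing table layout (same grid/probe/mask/
# scaling); used for external-set prediction. Excluded electrostatic values in
# the new rows are filled with the reference table's column means.
field_rows_for <- function(table, mols) {
  tab2 <- compute_field_table(mols, table$grid, table$probe, table$cutoff,
                              exclude_electrostatics = table$exclude_electrostatics,
                              exclude_fill = table$efill)
  tab2$mask <- table$mask
  tab2$scaling <- table$scaling
  scaled_matrix(tab2)
}
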