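# The regular CoMFA lattice. Axis ranges run from (min coordinate - margin) to
# (max coordinate + margin) over all atoms of all aligned molecules; the
# origin sits exactly at the low corner (no rounding to whole Angstrom) and
# counts are floor(range/spacing) + 1 per axis. Points are indexed 0-based,
# point(i,j,k) = origin + (i,j,k) * spacing, and serialized in (i,j,k) raster
# order with k fastest.

#' Construct a grid specification
#'
#' @param origin numeric length-3 low corner (Angstrom).
#' @param spacing lattice spacing in Angstrom (> 0).
#' @param counts integer length-3 number of points per axis (>= 1).
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(origin, spacing, counts) {
  stopifnot(length(origin) == 3, length(counts) == 3, spacing > 0,
            all(counts >= 1))
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 counts = as.integer(counts)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d points, spacing %.3f A, origin (%.3f, %.3f, %.3f)\n",
              x$counts[1], x$counts[2], x$counts[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Number of lattice points of a grid
#' @param grid a `grid_spec`.
#' @return integer point count.
#' @export
n_grid_points <- function(grid) prod(grid$counts)

#' Coordinates of all lattice points
#'
#' @param grid a `grid_spec`.
#' @return an (nx*ny*nz) x 3 matrix in raster order (i slowest, k fastest).
#' @export
grid_points <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  ii <- rep(0:(grid$counts[1] - 1), each = grid$counts[2] * grid$counts[3])
  jj <- rep(rep(0:(grid$counts[2] - 1), each = grid$counts[3]), grid$counts[1])
  kk <- rep(0:(grid$counts[3] - 1), grid$counts[1] * grid$counts[2])
  cbind(x = grid$origin[1] + ii * grid$spacing,
        y = grid$origin[2] + jj * grid$spacing,
        z = grid$origin[3] + kk * grid$spacing)
}

#' Build the lattice around an aligned series
#'
#' @param aligned list of aligned `molecule3d` objects (or a single one).
#' @param spacing lattice spacing in Angstrom (default 2.0).
#' @param margin extension of the lattice walls beyond the extreme atom
#'   coordinates, in Angstrom (default 4.0, applied in all directions).
#' @return a `grid_spec` enclosing every atom of every molecule.
#' @export
build_grid <- function(aligned, spacing = 2.0, margin = 4.0) {
  if (inherits(aligned, "molecule3d")) aligned <- list(aligned)
  if (length(aligned) == 0) stop("cannot build a grid around an empty set")
  stopifnot(spacing > 0, margin >= 0)
  xyz <- do.call(rbind, lapply(aligned, coords))
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  counts <- floor((hi - lo) / spacing + 1e-9) + 1
  grid_spec(origin = lo, spacing = spacing, counts = counts)
}
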