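# The 3D molecule container used throughout the field pipeline: elements,
# coordinates in Angstrom, partial charges in e, and Tripos-style van der
# Waals parameters (radius in Angstrom, well depth in kcal/mol).

# Tripos-force-field-style vdW parameters (Clark, Cramer & Van Opdenbosch
# style values); radius Angstrom, epsilon kcal/mol.
.VDW_TABLE <- data.frame(
  element = c("C",    "H",   "N",    "O",    "S",    "F",    "Cl",   "Br",  "I"),
  radius  = c(1.70,   1.50,  1.55,   1.52,   1.80,   1.47,   1.75,   1.85,  1.98),
  epsilon = c(0.107,  0.042, 0.095,  0.116,  0.314,  0.109,  0.314,  0.434, 0.623),
  stringsAsFactors = FALSE
)

#' Van der Waals parameter table used by the field engine
#'
#' @return data.frame with columns `element`, `radius` (Angstrom) and
#'   `epsilon` (kcal/mol).
#' @export
vdw_params <- function() .VDW_TABLE

#' Construct a 3D molecule
#'
#' @param id compound label.
#' @param atoms data.frame with columns `element`, `x`, `y`, `z` and
#'   optionally `charge` (partial charges in e; default 0).
#' @param bonds data.frame with columns `i`, `j`, `order`.
#' @param seed integer embedding seed recorded with the structure (or `NA`).
#' @return an object of class `molecule3d`. Van der Waals `radius`/`epsilon`
#'   columns are filled from [vdw_params()].
#' @export
molecule3d <- function(id, atoms, bonds = data.frame(i = integer(0), j = integer(0),
                                                     order = numeric(0)),
                       seed = NA_integer_) {
  stopifnot(is.data.frame(atoms), all(c("element", "x", "y", "z") %in% names(atoms)))
  if (!"charge" %in% names(atoms)) atoms$charge <- 0
  unknown <- setdiff(unique(atoms$element), .VDW_TABLE$element)
  if (length(unknown) > 0)
    stop("no van der Waals parameters for element(s): ",
         paste(unknown, collapse = ", "))
  k <- match(atoms$element, .VDW_TABLE$element)
  atoms$radius <- .VDW_TABLE$radius[k]
  atoms$epsilon <- .VDW_TABLE$epsilon[k]
  if (nrow(bonds) > 0) {
    stopifnot(all(bonds$i >= 1), all(bonds$j >= 1),
              all(bonds$i <= nrow(atoms)), all(bonds$j <= nrow(atoms)))
  }
  structure(list(id = id, atoms = atoms, bonds = bonds, seed = seed),
            class = "molecule3d")
}

#' @export
print.molecule3d <- function(x, ...) {
  cat(sprintf("<molecule3d> %s: %d atoms, %d bonds, seed %s\n",
              x$id, nrow(x$atoms), nrow(x$bonds), as.character(x$seed)))
  invisible(x)
}

#' Atom coordinates of a molecule as a matrix
#'
#' @param mol a `molecule3d`.
#' @return numeric matrix with one row per atom and columns x, y, z (Angstrom).
#' @export
coords <- function(mol) {
  stopifnot(inherits(mol, "molecule3d"))
  as.matrix(mol$atoms[, c("x", "y", "z")])
}

# Replace coordinates, keeping everything else.
set_coords <- function(mol, xyz) {
  stopifnot(inherits(mol, "molecule3d"), nrow(xyz) == nrow(mol$atoms))
  mol$atoms$x <- xyz[, 1]; mol$atoms$y <- xyz[, 2]; mol$atoms$z <- xyz[, 3]
  mol
}

# Heavy-atom (non hydrogen) index vector.
heavy_atoms <- function(mol) which(mol$atoms$element != "H")

# Convert a molecule3d to the molgraph layout used by the charge model.
as_molgraph <- function(mol) {
  stopifnot(inherits(mol, "molecule3d"))
  structure(list(
    atoms = data.frame(element = mol$atoms$element, aromatic = FALSE,
                       charge = if ("formal_charge" %in% names(mol$atoms))
                         mol$atoms$formal_charge else 0L,
                       hcount = 0L, stringsAsFactors = FALSE),
    bonds = mol$bonds
  ), class = "molgraph")
}
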