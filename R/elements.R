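# Element parameter tables. Average weights are used for percent composition
# (matching CHN microanalysis software of the era), monoisotopic masses for
# [M+H]+ m/z. Both carried to >= 4 decimals; the element set is the one the
# compound series can contain.

.AVG_MASS <- c(
  H = 1.00794, C = 12.0107, N = 14.0067, O = 15.9994,
  F = 18.9984032, S = 32.065, Cl = 35.4527, Br = 79.904
)

.MONO_MASS <- c(
  H = 1.0078250319, C = 12.0, N = 14.0030740052, O = 15.9949146221,
  F = 18.9984032, S = 31.97207069, Cl = 34.96885271, Br = 78.9183376
)

.PROTON_MASS <- 1.00727646688

#' Molecular formula object
#'
#' A molecular formula is a named count vector over the supported element set
#' (`C`, `H`, `N`, `O`, `S`, `F`, `Cl`, `Br`) plus an integer net charge.
#'
#' @param counts named integer vector of element counts (names are element
#'   symbols; counts must be non-negative and at least one positive).
#' @param charge integer net charge in elementary charges.
#' @return an object of class `mol_formula`.
#' @examples
#' mol_formula(c(C = 18, H = 18, F = 1, N = 3, S = 1))
#' @export
mol_formula <- function(counts, charge = 0L) {
  if (length(counts) == 0 || is.null(names(counts)) || any(names(counts) == ""))
    stop("formula counts must be a named vector")
  counts <- counts[counts != 0]
  if (length(counts) == 0) stop("formula must contain at least one element")
  unknown <- setdiff(names(counts), names(.AVG_MASS))
  if (length(unknown) > 0)
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("element counts must be non-negative integers")
  # canonical Hill order: C, H, then alphabetical
  sym <- names(counts)
  rest <- sort(setdiff(sym, c("C", "H")))
  ord <- c(intersect(c("C", "H"), sym), rest)
  structure(list(counts = stats::setNames(as.integer(counts[ord]), ord),
                 charge = as.integer(charge)),
            class = "mol_formula")
}

#' @export
format.mol_formula <- function(x, ...) {
  s <- paste0(names(x$counts), ifelse(x$counts > 1, x$counts, ""), collapse = "")
  if (x$charge != 0)
    s <- paste0(s, ifelse(x$charge > 0, "+", "-"),
                ifelse(abs(x$charge) > 1, abs(x$charge), ""))
  s
}

#' @export
print.mol_formula <- function(x, ...) {
  cat("<mol_formula>", format(x), "\n")
  invisible(x)
}

#' @export
`==.mol_formula` <- function(e1, e2) {
  identical(format(e1), format(e2))
}

#' Parse a Hill-notation molecular formula string
#'
#' @param x a formula string such as `"C18H18FN3S"`.
#' @return a [mol_formula()] object.
#' @examples
#' parse_formula("C19H21N3OS")
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  toks <- regmatches(x, gregexpr("([A-Z][a-z]?)([0-9]*)", x))[[1]]
  if (sum(nchar(toks)) != nchar(x))
    stop("unparsable formula string: ", x)
  sym <- sub("[0-9]*$", "", toks)
  n <- as.integer(sub("^[A-Za-z]+", "", paste0(toks, "")))
  n[is.na(n)] <- 1L
  counts <- tapply(n, sym, sum)
  mol_formula(stats::setNames(as.integer(counts), names(counts)))
}

#' Percent mass composition of a molecular formula
#'
#' Uses standard average atomic weights; the returned percentages sum to 100.
#'
#' @param formula a [mol_formula()] object.
#' @return named numeric vector of mass percentages per element.
#' @examples
#' percent_composition(parse_formula("C18H18FN3S"))["C"]  # 66.03
#' @export
percent_composition <- function(formula) {
  stopifnot(inherits(formula, "mol_formula"))
  masses <- .AVG_MASS[names(formula$counts)] * formula$counts
  100 * masses / sum(masses)
}

#' Average molecular weight of a formula
#'
#' @param formula a [mol_formula()] object.
#' @return molecular weight in g/mol using average atomic weights.
#' @export
average_mass <- function(formula) {
  stopifnot(inherits(formula, "mol_formula"))
  sum(.AVG_MASS[names(formula$counts)] * formula$counts)
}

#' Monoisotopic m/z of the protonated molecule
#'
#' Returns the m/z of `[M+H]+` computed from most-abundant-isotope masses.
#'
#' @param formula a [mol_formula()] object describing the neutral molecule M.
#' @return m/z in Da of the singly protonated molecule.
#' @examples
#' protonated_monoisotopic_mz(parse_formula("C18H18FN3S"))  # 328.13
#' @export
protonated_monoisotopic_mz <- function(formula) {
  stopifnot(inherits(formula, "mol_formula"))
  if (formula$charge != 0)
    stop("protonated m/z is defined for a neutral formula")
  sum(.MONO_MASS[names(formula$counts)] * formula$counts) + .PROTON_MASS
}
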