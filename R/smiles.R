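# A small SMILES reader covering the organic subset (B, C, N, O, P, S, F, Cl,
# Br, I), bracket atoms with explicit H count and charge, branches, ring
# closures (including %nn) and aromatic lowercase atoms. It exists because no
# R cheminformatics package is available in the target environment; packaged
# structures are shipped in Kekule form so aromatic perception is never
# load-bearing for the shipped dataset.
#
# Implicit hydrogen rules:
#   * bracket atoms carry exactly the H count written (default 0);
#   * organic-subset aliphatic atoms get the smallest standard valence that
#     covers the bond-order sum (C 4; N 3/5; O 2; S 2/4/6; P 3/5; halogens 1;
#     B 3), aromatic bonds counting 1.5;
#   * aromatic carbon gets max(0, 3 - degree) hydrogens, other aromatic
#     atoms none unless written in brackets (e.g. [nH]).

.ORGANIC <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.STD_VALENCE <- list(B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5),
                     S = c(2, 4, 6), F = 1, Cl = 1, Br = 1, I = 1)

.smiles_error <- function(smiles, pos, what) {
  stop(sprintf("cannot parse SMILES '%s': %s at position %d (near '%s')",
               smiles, what, pos,
               substr(smiles, pos, min(nchar(smiles), pos + 4))), call. = FALSE)
}

.parse_bracket <- function(body, smiles, pos) {
  # [isotope? symbol chirality? Hn? charge? (:class)?]
  rx <- "^([0-9]*)([A-Za-z][a-z]?)(@{0,2})(H[0-9]*)?((?:\\+{1,3}|-{1,3}|\\+[0-9]+|-[0-9]+))?(:[0-9]+)?$"
  m <- regexec(rx, body)[[1]]
  if (m[1] == -1) .smiles_error(smiles, pos, paste0("bad bracket atom [", body, "]"))
  parts <- regmatches(body, regexec(rx, body))[[1]]
  sym <- parts[3]
  aromatic <- sym %in% c("b", "c", "n", "o", "p", "s")
  if (aromatic) sym <- toupper(sym)
  if (!sym %in% c(.ORGANIC, "H"))
    .smiles_error(smiles, pos, paste0("unsupported element '", sym, "'"))
  htok <- parts[5]
  h <- if (is.na(htok) || htok == "") 0L
       else if (htok == "H") 1L else as.integer(substring(htok, 2))
  ctok <- parts[6]
  charge <- 0L
  if (!is.na(ctok) && ctok != "") {
    if (grepl("^[+-][0-9]+$", ctok)) {
      charge <- as.integer(ctok)
    } else {
      charge <- nchar(ctok) * (if (substring(ctok, 1, 1) == "+") 1L else -1L)
    }
  }
  list(element = sym, aromatic = aromatic, hcount = h, charge = charge)
}

#' Parse a SMILES string into a molecular graph
#'
#' @param smiles a SMILES connectivity string.
#' @return a `molgraph` object: a list with `atoms` (data.frame with columns
#'   `element`, `aromatic`, `charge`, `hcount` giving per-atom hydrogen counts
#'   after applying the implicit-valence rules) and `bonds` (data.frame with
#'   columns `i`, `j`, `order`; aromatic bonds have order 1.5).
#' @examples
#' g <- parse_smiles("CC(=O)C")   # acetone
#' nrow(g$atoms)
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1 || is.na(smiles) || smiles == "")
    stop("smiles must be a single non-empty string")
  n <- nchar(smiles)
  el <- character(0); arom <- logical(0); chg <- integer(0); hexp <- integer(0)
  bi <- integer(0); bj <- integer(0); bo <- numeric(0)
  prev <- NA_integer_
  stack <- integer(0)
  pending_bond <- NA_real_
  ring <- list()    # key -> list(atom, order)
  i <- 1
  add_atom <- function(a) {
    el <<- c(el, a$element); arom <<- c(arom, a$aromatic)
    chg <<- c(chg, a$charge); hexp <<- c(hexp, a$hcount)
    idx <- length(el)
    if (!is.na(prev)) {
      o <- pending_bond
      if (is.na(o)) o <- if (arom[prev] && a$aromatic) 1.5 else 1
      bi <<- c(bi, prev); bj <<- c(bj, idx); bo <<- c(bo, o)
    }
    pending_bond <<- NA_real_
    prev <<- idx
    idx
  }
  close_ring <- function(key, pos) {
    if (is.na(prev)) .smiles_error(smiles, pos, "ring closure before any atom")
    if (!is.null(ring[[key]])) {
      open <- ring[[key]]
      o <- pending_bond
      if (is.na(o)) o <- open$order
      if (is.na(o)) o <- if (arom[open$atom] && arom[prev]) 1.5 else 1
      if (open$atom == prev) .smiles_error(smiles, pos, "self ring closure")
      bi <<- c(bi, open$atom); bj <<- c(bj, prev); bo <<- c(bo, o)
      ring[[key]] <<- NULL
    } else {
      ring[[key]] <- list(atom = prev, order = pending_bond)
      ring <<- ring
    }
    pending_bond <<- NA_real_
  }
  while (i <= n) {
    ch <- substr(smiles, i, i)
    two <- substr(smiles, i, i + 1)
    if (ch == "[") {
      j <- regexpr("]", substring(smiles, i), fixed = TRUE)
      if (j == -1) .smiles_error(smiles, i, "unclosed bracket")
      add_atom(.parse_bracket(substr(smiles, i + 1, i + j - 2), smiles, i))
      i <- i + j
    } else if (two %in% c("Cl", "Br")) {
      add_atom(list(element = two, aromatic = FALSE, hcount = NA_integer_, charge = 0L))
      i <- i + 2
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      add_atom(list(element = ch, aromatic = FALSE, hcount = NA_integer_, charge = 0L))
      i <- i + 1
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      add_atom(list(element = toupper(ch), aromatic = TRUE, hcount = NA_integer_, charge = 0L))
      i <- i + 1
    } else if (ch %in% c("-", "/", "\\")) {
      pending_bond <- 1; i <- i + 1
    } else if (ch == "=") {
      pending_bond <- 2; i <- i + 1
    } else if (ch == "#") {
      pending_bond <- 3; i <- i + 1
    } else if (ch == ":") {
      pending_bond <- 1.5; i <- i + 1
    } else if (ch == "(") {
      if (is.na(prev)) .smiles_error(smiles, i, "branch before any atom")
      stack <- c(stack, prev); i <- i + 1
    } else if (ch == ")") {
      if (length(stack) == 0) .smiles_error(smiles, i, "unmatched ')'")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1
    } else if (grepl("^[0-9]$", ch)) {
      close_ring(ch, i); i <- i + 1
    } else if (ch == "%") {
      key <- substr(smiles, i + 1, i + 2)
      if (!grepl("^[0-9]{2}$", key)) .smiles_error(smiles, i, "bad %nn ring closure")
      close_ring(key, i); i <- i + 3
    } else if (ch == ".") {
      prev <- NA_integer_; pending_bond <- NA_real_; i <- i + 1
    } else {
      .smiles_error(smiles, i, paste0("unexpected token '", ch, "'"))
    }
  }
  if (length(stack) > 0) stop("cannot parse SMILES '", smiles, "': unclosed branch", call. = FALSE)
  if (length(ring) > 0) stop("cannot parse SMILES '", smiles, "': unclosed ring bond(s)", call. = FALSE)
  if (length(el) == 0) stop("cannot parse SMILES '", smiles, "': no atoms", call. = FALSE)

  hcount <- hexp
  deg <- numeric(length(el))
  osum <- numeric(length(el))
  if (length(bi) > 0) {
    for (k in seq_along(bi)) {
      deg[bi[k]] <- deg[bi[k]] + 1; deg[bj[k]] <- deg[bj[k]] + 1
      osum[bi[k]] <- osum[bi[k]] + bo[k]; osum[bj[k]] <- osum[bj[k]] + bo[k]
    }
  }
  for (a in seq_along(el)) {
    if (!is.na(hcount[a])) next  # bracket atom: explicit count
    if (arom[a]) {
      hcount[a] <- if (el[a] == "C") max(0L, 3L - as.integer(deg[a])) else 0L
    } else {
      val <- .STD_VALENCE[[el[a]]]
      if (is.null(val)) .smiles_error(smiles, 1, paste0("no valence model for ", el[a]))
      need <- ceiling(osum[a])
      fit <- val[val >= need]
      hcount[a] <- if (length(fit) == 0) 0L else as.integer(fit[1] - need)
    }
  }
  structure(list(
    atoms = data.frame(element = el, aromatic = arom, charge = chg,
                       hcount = as.integer(hcount), stringsAsFactors = FALSE),
    bonds = data.frame(i = bi, j = bj, order = bo)
  ), class = "molgraph")
}

#' Molecular formula of a SMILES string
#'
#' Element counts include implicit hydrogens; the net charge is the sum of the
#' atomic formal charges.
#'
#' @param smiles a SMILES connectivity string.
#' @return a [mol_formula()] object.
#' @examples
#' format(formula_of("C"))            # "CH4"
#' format(formula_of("CC(=O)C"))      # "C3H6O"
#' @export
formula_of <- function(smiles) {
  g <- parse_smiles(smiles)
  counts <- table(g$atoms$element)
  counts <- stats::setNames(as.integer(counts), names(counts))
  h <- sum(g$atoms$hcount)
  counts["H"] <- (if ("H" %in% names(counts)) counts[["H"]] else 0L) + h
  mol_formula(counts, charge = sum(g$atoms$charge))
}

# Add explicit hydrogen atoms to a molgraph (used by the charge model).
expand_hydrogens <- function(g) {
  stopifnot(inherits(g, "molgraph"))
  atoms <- g$atoms
  bonds <- g$bonds
  nh <- atoms$hcount
  for (a in seq_len(nrow(atoms))) {
    if (nh[a] > 0) {
      for (k in seq_len(nh[a])) {
        atoms <- rbind(atoms, data.frame(element = "H", aromatic = FALSE,
                                         charge = 0L, hcount = 0L))
        bonds <- rbind(bonds, data.frame(i = a, j = nrow(atoms), order = 1))
      }
    }
  }
  atoms$hcount <- 0L
  structure(list(atoms = atoms, bonds = bonds), class = "molgraph")
}
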