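# Rigid atom-by-atom least-squares alignment of the series onto a template
# molecule via a shared-core substructure match (element-labelled subgraph
# monomorphism) and Kabsch superposition.

# Default shared core: the 4,5-dihydro-1H-pyrazole ring, its C3 and C5 aryl
# attachment carbons and the exocyclic carbon on N1 (8 heavy atoms).
.DEFAULT_CORE <- "CN1N=C(C)CC1C"

.heavy_graph <- function(elements, bonds, keep) {
  idx <- which(keep)
  remap <- match(seq_along(elements), idx)
  b <- bonds[keep[bonds$i] & keep[bonds$j], , drop = FALSE]
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(b) > 0)
    g <- igraph::add_edges(g, rbind(remap[b$i], remap[b$j]))
  list(graph = g, elements = elements[idx], orig = idx)
}

.pattern_graph <- function(core_pattern) {
  if (is.character(core_pattern)) core_pattern <- parse_smiles(core_pattern)
  stopifnot(inherits(core_pattern, "molgraph"))
  .heavy_graph(core_pattern$atoms$element, core_pattern$bonds,
               core_pattern$atoms$element != "H")
}

#' Find the shared-core substructure match in a molecule
#'
#' Matches the heavy-atom graph of `core_pattern` (a SMILES string or
#' `molgraph`) into the molecule by element-labelled subgraph monomorphism
#' (bond orders are ignored). Among symmetric matches the lexicographically
#' smallest molecule-atom index sequence (in pattern-atom order) is returned,
#' making the choice deterministic.
#'
#' @param mol a `molecule3d` or `molgraph`.
#' @param core_pattern core substructure; default is the
#'   4,5-dihydro-1H-pyrazole core of the packaged series plus its three
#'   attachment carbons (8 atoms).
#' @return a `core_match`: data.frame with columns `core` (pattern atom) and
#'   `atom` (molecule atom index).
#' @export
find_core <- function(mol, core_pattern = .DEFAULT_CORE) {
  if (inherits(mol, "molecule3d")) {
    tg <- .heavy_graph(mol$atoms$element, mol$bonds, mol$atoms$element != "H")
  } else if (inherits(mol, "molgraph")) {
    tg <- .heavy_graph(mol$atoms$element, mol$bonds, mol$atoms$element != "H")
  } else stop("mol must be a molecule3d or molgraph")
  pg <- .pattern_graph(core_pattern)
  np <- length(pg$elements)
  if (np < 3) stop("core pattern must have at least 3 atoms")
  domains <- lapply(pg$elements, function(e) which(tg$elements == e))
  if (any(vapply(domains, length, 1L) == 0))
    stop("core absent: no ", setdiff(pg$elements, tg$elements)[1],
         " atom in molecule", call. = FALSE)
  maps <- igraph::subgraph_isomorphisms(pg$graph, tg$graph, method = "lad",
                                        induced = FALSE, domains = domains)
  if (length(maps) == 0) stop("core absent", call. = FALSE)
  seqs <- lapply(maps, function(m) tg$orig[as.integer(m)])
  ord <- do.call(order, as.data.frame(do.call(rbind, seqs)))
  best <- seqs[[ord[1]]]
  structure(data.frame(core = seq_len(np), atom = best), class = c("core_match",
                                                                   "data.frame"))
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation (determinant +1; reflections disallowed) and
#' translation minimizing the RMSD between two equal-length point sets.
#'
#' @param mobile n x 3 matrix of points to move.
#' @param target n x 3 matrix of reference points.
#' @return list with `rotation` (3 x 3), `translation` (length 3) such that
#'   `mobile %*% t(rotation) + translation` best fits `target`, and `rmsd`
#'   (Angstrom).
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (nrow(mobile) != nrow(target) || ncol(mobile) != 3 || ncol(target) != 3)
    stop("mobile and target must be equal-length n x 3 point sets")
  if (nrow(mobile) < 3)
    stop("degenerate geometry: need at least 3 points")
  cm <- colMeans(mobile); ct <- colMeans(target)
  P <- sweep(mobile, 2, cm); Q <- sweep(target, 2, ct)
  if (svd(P)$d[2] < 1e-8 * max(1, svd(P)$d[1]) ||
      svd(Q)$d[2] < 1e-8 * max(1, svd(Q)$d[1]))
    stop("degenerate geometry: points are collinear")
  s <- svd(t(P) %*% Q)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  moved <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  list(rotation = R, translation = as.numeric(ct - R %*% cm), rmsd = rmsd)
}

# Apply a rigid transform to all atoms of a molecule.
.transform_mol <- function(mol, rotation, translation) {
  xyz <- coords(mol) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  set_coords(mol, xyz)
}

#' Rigidly align a compound series onto a template molecule
#'
#' Every molecule is superimposed onto the template by a least-squares fit of
#' its core-substructure atoms (pattern-ordered pairs); the template itself is
#' left untouched.
#'
#' @param mols named list of `molecule3d` (names or `$id` must contain
#'   `template_id`).
#' @param template_id id of the reference molecule (default `"D5"`, the most
#'   active compound of the packaged series).
#' @param core_pattern shared core passed to [find_core()].
#' @return list of aligned molecules in input order, each carrying a
#'   `core_rmsd` attribute; the whole list carries an `alignment_report`
#'   attribute (data.frame `id`, `core_rmsd`).
#' @export
align_series <- function(mols, template_id = "D5", core_pattern = .DEFAULT_CORE) {
  ids <- vapply(mols, function(m) m$id, character(1))
  ti <- match(template_id, ids)
  if (is.na(ti)) stop("template '", template_id, "' not present in series")
  failed <- character(0)
  matches <- vector("list", length(mols))
  for (k in seq_along(mols)) {
    matches[k] <- list(tryCatch(find_core(mols[[k]], core_pattern),
                                error = function(e) NULL))
    if (is.null(matches[[k]])) failed <- c(failed, ids[k])
  }
  if (length(failed) > 0)
    stop("core absent in compound(s): ", paste(failed, collapse = ", "))
  tmpl_xyz <- coords(mols[[ti]])[matches[[ti]]$atom, , drop = FALSE]
  out <- mols
  rmsds <- numeric(length(mols))
  for (k in seq_along(mols)) {
    if (k == ti) { rmsds[k] <- 0; next }
    mob <- coords(mols[[k]])[matches[[k]]$atom, , drop = FALSE]
    fit <- kabsch_superpose(mob, tmpl_xyz)
    out[[k]] <- .transform_mol(mols[[k]], fit$rotation, fit$translation)
    rmsds[k] <- fit$rmsd
    attr(out[[k]], "core_rmsd") <- fit$rmsd
  }
  attr(out[[ti]], "core_rmsd") <- 0
  attr(out, "alignment_report") <- data.frame(id = ids, core_rmsd = rmsds,
                                              stringsAsFactors = FALSE)
  names(out) <- ids
  out
}
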