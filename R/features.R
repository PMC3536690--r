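# Simplified pharmacophore feature perception and mapping against a fixed
# feature hypothesis. The rule set (documented here, in-code, deliberately
# simple and deterministic):
#
#   AROMATIC_RING  5/6-membered ring of C/N/O/S atoms in which every ring atom
#                  either takes part in a ring double bond or is a divalent
#                  heteroatom; feature at the ring centroid. All-carbon
#                  aromatic rings additionally emit a HYDROPHOBE at the same
#                  centroid (ring hydrophobe).
#   HBA            neutral N or O with no bonded hydrogen and heavy-atom
#                  degree <= 2 (lone pair available, no donor role).
#   HYDROPHOBE     centroids of anchored apolar substituent clusters:
#                  connected sets of non-ring sp3 carbons whose neighbours are
#                  only C/H/halogen, together with halogen atoms; clusters
#                  whose centroids lie within 3.0 Angstrom are merged
#                  (single-linkage, order-independent); a cluster must be
#                  attached to at least one heavy atom outside itself, so an
#                  isolated alkane yields no feature.

.ring_atoms <- function(mol) {
  hg <- .heavy_graph(mol$atoms$element, mol$bonds, mol$atoms$element != "H")
  rings <- list()
  for (n in c(5L, 6L)) {
    cyc <- igraph::make_ring(n)
    maps <- tryCatch(
      igraph::subgraph_isomorphisms(cyc, hg$graph, method = "lad", induced = TRUE),
      error = function(e) list())
    for (m in maps) {
      v <- sort(hg$orig[as.integer(m)])
      key <- paste(v, collapse = ",")
      if (is.null(rings[[key]])) rings[[key]] <- v
    }
  }
  unname(rings)
}

.is_aromatic_ring <- function(mol, ring) {
  el <- mol$atoms$element[ring]
  if (!all(el %in% c("C", "N", "O", "S"))) return(FALSE)
  rb <- mol$bonds[mol$bonds$i %in% ring & mol$bonds$j %in% ring, , drop = FALSE]
  if (any(rb$order == 1.5)) return(TRUE)
  for (a in ring) {
    has_double <- any(rb$order >= 2 & (rb$i == a | rb$j == a))
    divalent_het <- el[match(a, ring)] %in% c("N", "O", "S")
    if (!has_double && !divalent_het) return(FALSE)
  }
  TRUE
}

#' Perceive pharmacophore features of a 3D molecule
#'
#' Applies the package's documented HBA / HYDROPHOBE / AROMATIC_RING rule set
#' (see source of this function). The result is independent of atom input
#' order.
#'
#' @param mol a `molecule3d`.
#' @return data.frame with columns `kind`, `x`, `y`, `z` (feature centers in
#'   Angstrom); zero rows when nothing is perceived.
#' @export
perceive_features <- function(mol) {
  stopifnot(inherits(mol, "molecule3d"))
  a <- mol$atoms; b <- mol$bonds
  xyz <- coords(mol)
  feats <- data.frame(kind = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), stringsAsFactors = FALSE)
  add <- function(kind, center) {
    feats <<- rbind(feats, data.frame(kind = kind, x = center[1], y = center[2],
                                      z = center[3], stringsAsFactors = FALSE))
  }
  nbrs <- function(k) c(b$j[b$i == k], b$i[b$j == k])
  fc <- if ("formal_charge" %in% names(a)) a$formal_charge else rep(0L, nrow(a))

  rings <- .ring_atoms(mol)
  ring_members <- unique(unlist(rings))
  for (r in rings) {
    if (.is_aromatic_ring(mol, r)) {
      ctr <- colMeans(xyz[r, , drop = FALSE])
      add("AROMATIC_RING", ctr)
      if (all(a$element[r] == "C")) add("HYDROPHOBE", ctr)
    }
  }

  for (k in which(a$element %in% c("N", "O"))) {
    nb <- nbrs(k)
    heavy_nb <- nb[a$element[nb] != "H"]
    if (fc[k] == 0 && !any(a$element[nb] == "H") && length(heavy_nb) <= 2)
      add("HBA", xyz[k, ])
  }

  halog <- c("F", "Cl", "Br", "I")
  qual <- logical(nrow(a))
  for (k in seq_len(nrow(a))) {
    e <- a$element[k]
    if (e %in% halog) { qual[k] <- TRUE; next }
    if (e != "C" || k %in% ring_members) next
    has_multiple <- any(b$order[(b$i == k | b$j == k)] >= 1.5)
    nb_el <- a$element[nbrs(k)]
    qual[k] <- !has_multiple && all(nb_el %in% c("C", "H", halog))
  }
  qk <- which(qual)
  if (length(qk) > 0 && sum(a$element != "H") > 1) {
    sub <- igraph::make_empty_graph(n = length(qk), directed = FALSE)
    bb <- b[b$i %in% qk & b$j %in% qk, , drop = FALSE]
    if (nrow(bb) > 0)
      sub <- igraph::add_edges(sub, rbind(match(bb$i, qk), match(bb$j, qk)))
    comp <- igraph::components(sub)$membership
    clusters <- split(qk, comp)
    anchored <- vapply(clusters, function(cl) {
      ext <- setdiff(unlist(lapply(cl, nbrs)), cl)
      any(a$element[ext] != "H")
    }, logical(1))
    clusters <- clusters[anchored]
    if (length(clusters) > 0) {
      ctrs <- t(vapply(clusters, function(cl)
        colMeans(xyz[cl, , drop = FALSE]), numeric(3)))
      merged <- seq_len(nrow(ctrs))  # single-linkage closure at 3.0 A
      repeat {
        done <- TRUE
        for (p in seq_len(nrow(ctrs))) for (q in seq_len(nrow(ctrs))) {
          if (merged[p] != merged[q] &&
              sqrt(sum((ctrs[p, ] - ctrs[q, ])^2)) < 3.0) {
            merged[merged == merged[q]] <- merged[p]; done <- FALSE
          }
        }
        if (done) break
      }
      for (gid in unique(merged)) {
        cl <- unlist(clusters[merged == gid])
        add("HYDROPHOBE", colMeans(xyz[cl, , drop = FALSE]))
      }
    }
  }
  feats[order(feats$kind, round(feats$x, 6), round(feats$y, 6),
              round(feats$z, 6)), , drop = FALSE]
}

#' Build a pharmacophore hypothesis from a molecule's perceived features
#'
#' The packaged five-feature hypothesis of the series (2 hydrogen-bond
#' acceptors + 3 hydrophobic centers) is obtained by applying this to the
#' aligned reference compound D5.
#'
#' @param mol a `molecule3d`.
#' @param tolerance feature tolerance radius in Angstrom (> 0).
#' @param kinds feature kinds retained in the hypothesis.
#' @return a `pharmacophore_hypothesis`: data.frame with columns `kind`, `x`,
#'   `y`, `z`, `tolerance`.
#' @export
hypothesis_from_molecule <- function(mol, tolerance = 1.6,
                                     kinds = c("HBA", "HYDROPHOBE")) {
  stopifnot(tolerance > 0)
  f <- perceive_features(mol)
  f <- f[f$kind %in% kinds, , drop = FALSE]
  if (nrow(f) == 0) stop("no features of the requested kinds perceived")
  f$tolerance <- tolerance
  rownames(f) <- NULL
  class(f) <- c("pharmacophore_hypothesis", "data.frame")
  f
}

#' Map perceived features onto a pharmacophore hypothesis
#'
#' Finds the one-to-one assignment of kind-compatible molecule features to
#' hypothesis features minimizing the RMS of center-to-center distances, with
#' every matched distance within the hypothesis tolerance. The search is an
#' exact enumeration over assignments (feature counts are small), so there is
#' no greedy-order ambiguity.
#'
#' @param features data.frame from [perceive_features()].
#' @param hypothesis a `pharmacophore_hypothesis`.
#' @return `NULL` when some hypothesis feature cannot be matched; otherwise a
#'   list with `assignment` (data.frame `hypothesis_feature`,
#'   `molecule_feature`, `distance`) and `fit_rmsd` (Angstrom).
#' @export
map_to_hypothesis <- function(features, hypothesis) {
  stopifnot(inherits(hypothesis, "pharmacophore_hypothesis"), nrow(hypothesis) > 0)
  nh <- nrow(hypothesis)
  cand <- vector("list", nh)
  for (h in seq_len(nh)) {
    same <- which(features$kind == hypothesis$kind[h])
    if (length(same) > 0) {
      d <- sqrt((features$x[same] - hypothesis$x[h])^2 +
                (features$y[same] - hypothesis$y[h])^2 +
                (features$z[same] - hypothesis$z[h])^2)
      keep <- d <= hypothesis$tolerance[h]
      cand[[h]] <- data.frame(f = same[keep], d = d[keep])
    } else cand[[h]] <- data.frame(f = integer(0), d = numeric(0))
    if (nrow(cand[[h]]) == 0) return(NULL)
  }
  best <- NULL; best_ss <- Inf
  assign <- integer(nh); dists <- numeric(nh)
  recurse <- function(h, used, ss) {
    if (ss >= best_ss) return()
    if (h > nh) {
      best_ss <<- ss; best <<- list(assign = assign, dists = dists)
      return()
    }
    cc <- cand[[h]]
    for (r in seq_len(nrow(cc))) {
      if (cc$f[r] %in% used) next
      assign[h] <<- cc$f[r]; dists[h] <<- cc$d[r]
      recurse(h + 1, c(used, cc$f[r]), ss + cc$d[r]^2)
    }
  }
  recurse(1, integer(0), 0)
  if (is.null(best)) return(NULL)
  list(assignment = data.frame(hypothesis_feature = seq_len(nh),
                               molecule_feature = best$assign,
                               distance = best$dists),
       fit_rmsd = sqrt(best_ss / nh))
}
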