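# Minimal MDL V2000 SDF reader/writer, sufficient for structures produced by
# the embedding backend and for user-supplied series. Handles atom/bond blocks,
# "M  CHG" formal charges and ">  <tag>" data items.

#' Read a multi-record V2000 SDF file
#'
#' @param path path to an SDF file.
#' @return a list of `molecule3d` objects. Formal charges from `M  CHG` lines
#'   are stored in the `formal_charge` atom column; data items are attached as
#'   the `properties` attribute of each molecule. Partial charges default to 0
#'   (assign with [assign_gasteiger_charges()]).
#' @export
read_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- list()
  start <- 1
  for (k in which(lines == "$$$$")) {
    recs[[length(recs) + 1]] <- lines[start:(k - 1)]
    start <- k + 1
  }
  if (start <= length(lines) && any(nzchar(lines[start:length(lines)])))
    recs[[length(recs) + 1]] <- lines[start:length(lines)]
  lapply(recs, .parse_molfile)
}

.parse_molfile <- function(lines) {
  if (length(lines) < 4) stop("truncated molfile record")
  id <- trimws(lines[1])
  counts <- lines[4]
  natoms <- as.integer(substr(counts, 1, 3))
  nbonds <- as.integer(substr(counts, 4, 6))
  if (is.na(natoms) || is.na(nbonds)) stop("bad V2000 counts line: ", counts)
  at <- lines[5:(4 + natoms)]
  atoms <- data.frame(
    element = trimws(substr(at, 32, 34)),
    x = as.numeric(substr(at, 1, 10)),
    y = as.numeric(substr(at, 11, 20)),
    z = as.numeric(substr(at, 21, 30)),
    stringsAsFactors = FALSE
  )
  atoms$charge <- 0
  atoms$formal_charge <- 0L
  bonds <- data.frame(i = integer(0), j = integer(0), order = numeric(0))
  if (nbonds > 0) {
    bl <- lines[(5 + natoms):(4 + natoms + nbonds)]
    bonds <- data.frame(
      i = as.integer(substr(bl, 1, 3)),
      j = as.integer(substr(bl, 4, 6)),
      order = as.numeric(substr(bl, 7, 9))
    )
    bonds$order[bonds$order == 4] <- 1.5  # aromatic bond code
  }
  props <- list()
  rest <- if (length(lines) > 4 + natoms + nbonds)
    lines[(5 + natoms + nbonds):length(lines)] else character(0)
  for (ln in rest[startsWith(rest, "M  CHG")]) {
    f <- as.integer(strsplit(trimws(substring(ln, 7)), "[[:space:]]+")[[1]])
    nn <- f[1]
    for (q in seq_len(nn)) {
      atoms$formal_charge[f[2 * q]] <- f[2 * q + 1]
    }
  }
  tag_at <- grep("^> *<", rest)
  for (t in tag_at) {
    tag <- sub("^> *<([^>]+)>.*$", "\\1", rest[t])
    val <- character(0)
    u <- t + 1
    while (u <= length(rest) && nzchar(rest[u]) && rest[u] != "$$$$") {
      val <- c(val, rest[u]); u <- u + 1
    }
    props[[tag]] <- paste(val, collapse = "\n")
  }
  mol <- molecule3d(id = id, atoms = atoms, bonds = bonds,
                    seed = if (!is.null(props$embed_seed))
                      as.integer(props$embed_seed) else NA_integer_)
  attr(mol, "properties") <- props
  mol
}

#' Write molecules to a multi-record V2000 SDF file
#'
#' Partial charges and the embedding seed are written as data items
#' (`partial_charges`, `embed_seed`); formal charges as `M  CHG` lines.
#'
#' @param mols a `molecule3d` or list of them.
#' @param path output file path.
#' @param extra_props optional named list (per molecule id) of additional data
#'   items, each a named character vector.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path, extra_props = NULL) {
  if (inherits(mols, "molecule3d")) mols <- list(mols)
  con <- file(path, "w")
  on.exit(close(con))
  for (mol in mols) {
    a <- mol$atoms
    n <- nrow(a); b <- mol$bonds
    writeLines(c(mol$id, "  comfar", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(b)), con)
    writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       a$x, a$y, a$z, a$element), con)
    if (nrow(b) > 0) {
      o <- ifelse(b$order == 1.5, 4, round(b$order))
      writeLines(sprintf("%3d%3d%3d  0", b$i, b$j, o), con)
    }
    fc <- if ("formal_charge" %in% names(a)) which(a$formal_charge != 0) else integer(0)
    if (length(fc) > 0) {
      writeLines(paste0("M  CHG", sprintf("%3d", length(fc)),
                        paste0(sprintf("%4d%4d", fc, a$formal_charge[fc]),
                               collapse = "")), con)
    }
    writeLines("M  END", con)
    writeLines(c("> <embed_seed>", as.character(mol$seed), ""), con)
    writeLines(c("> <partial_charges>",
                 paste(sprintf("%.6f", a$charge), collapse = " "), ""), con)
    ep <- extra_props[[mol$id]]
    for (tag in names(ep)) writeLines(c(sprintf("> <%s>", tag), ep[[tag]], ""), con)
    writeLines("$$$$", con)
  }
  invisible(path)
}
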