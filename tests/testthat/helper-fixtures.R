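# Shared fixtures, memoized so expensive stages (python embedding, the full
# packaged pipeline) run once per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# toy molecules embedded in one backend call
toy_mols <- function() cached("toys", {
  tab <- data.frame(
    id = c("ethane", "benzene", "anisole", "methane", "acetone"),
    smiles = c("CC", "C1=CC=CC=C1", "COC1=CC=CC=C1", "C", "CC(=O)C"),
    stringsAsFactors = FALSE)
  embed_series(tab, seed = 7)
})

# full packaged 46-compound pipeline (embed + align + fields + PLS + contours)
packaged_run <- function() cached("run", {
  t0 <- Sys.time()
  res <- run_comfa(seed = 42)
  attr(res, "elapsed_s") <- as.numeric(Sys.time() - t0, units = "secs")
  res
})

packaged_aligned <- function() packaged_run()$aligned

# synthetic noiseless congeneric series pushed through the whole 3D pipeline
synthetic_run <- function() cached("synthetic", {
  ser <- simulate_congeneric_series(series_spec(noise_sd = 0, seed = 5))
  mols <- embed_series(ser, seed = 11)
  aligned <- align_series(mols, template_id = ser$id[1])
  grid <- build_grid(aligned)
  table <- scale_comfa_std(filter_columns(compute_field_table(aligned, grid),
                                          min_sigma = 1.0))
  model <- fit_pls(scaled_matrix(table), ser$activity, 2)
  list(series = ser, aligned = aligned, grid = grid, table = table,
       model = model)
})

# an in-code field_table with known content, for unit tests that do not need
# real molecules
fake_field_table <- function(X, field, point = NULL) {
  np <- length(field) / 2
  structure(list(
    X = X, ids = rownames(X), field = field,
    point = if (is.null(point)) rep(seq_len(np), 2) else point,
    mask = rep(TRUE, ncol(X)),
    grid = grid_spec(c(0, 0, 0), 2, c(1, 1, length(field) / 2)),
    probe = probe_spec(), cutoff = 30, scaling = NULL,
    efill = rep(0, length(field) / 2), exclude_electrostatics = TRUE
  ), class = "field_table")
}

# single-atom toy molecule at given position
single_atom_mol <- function(element = "C", pos = c(0, 0, 0), charge = 0,
                            id = "toy") {
  m <- molecule3d(id, data.frame(element = element, x = pos[1], y = pos[2],
                                 z = pos[3], charge = charge))
  m
}
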