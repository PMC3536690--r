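# Synthetic data with the statistical structure the CoMFA analysis assumes:
# (a) abstract energy-like descriptor matrices whose response is a linear
# function of a few "signal" columns plus Gaussian noise, and (b) toy
# congeneric series on the dihydropyrazole scaffold whose activity is a known
# linear function of substituent bulk, so the whole 3D pipeline has a
# ground-truth recovery test. All generators are pure functions of their seed
# and parameters.

#' Simulate an energy-like field matrix with a planted linear signal
#'
#' Emulates the statistical structure of a CoMFA descriptor block: columns are
#' organized into contiguous blocks of `k_signal` columns sharing a latent
#' "region" factor (intra-block correlation `rho`), mirroring the strong
#' spatial correlation of neighboring lattice points; per-column spreads are
#' drawn uniformly from 0.5-8 kcal/mol and values clipped at +-30 like
#' truncated field energies. One randomly chosen block is the localized signal
#' region: its columns carry coefficient `beta`, and
#' `y = X beta_true + Normal(0, noise_sd)`.
#'
#' @param n rows (compounds), >= 8.
#' @param p columns, >= `k_signal` >= 1.
#' @param k_signal number of signal-carrying columns (= block size).
#' @param beta coefficient shared by the signal columns.
#' @param noise_sd Gaussian noise standard deviation on y.
#' @param seed integer seed.
#' @param rho intra-block correlation of the latent region structure.
#' @return a `synthetic_field_dataset`: list with `X`, `y`, `signal_columns`,
#'   `beta_true`, `noise_sd`, `seed`.
#' @export
simulate_field_dataset <- function(n, p, k_signal, beta, noise_sd, seed,
                                   rho = 0.7) {
  if (n < 8) stop("invalid dimensions: need n >= 8")
  if (k_signal < 1 || p < k_signal) stop("invalid dimensions: need p >= k_signal >= 1")
  stopifnot(rho >= 0, rho < 1)
  with_seed(seed, {
    n_block <- ceiling(p / k_signal)
    block <- rep(seq_len(n_block), each = k_signal)[seq_len(p)]
    F <- matrix(stats::rnorm(n * n_block), n, n_block)
    sds <- stats::runif(p, 0.5, 8)
    X <- sqrt(rho) * F[, block, drop = FALSE] +
      sqrt(1 - rho) * matrix(stats::rnorm(n * p), n, p)
    X <- pmin(pmax(sweep(X, 2, sds, "*"), -30), 30)
    signal_block <- sample.int(n_block, 1)
    signal <- which(block == signal_block)
    beta_true <- numeric(p)
    beta_true[signal] <- beta
    y <- as.numeric(X %*% beta_true) + stats::rnorm(n, 0, noise_sd)
    structure(list(X = X, y = y, signal_columns = signal,
                   beta_true = beta_true, noise_sd = noise_sd,
                   seed = as.integer(seed)),
              class = "synthetic_field_dataset")
  })
}

# default substituent set: apolar groups with distinct nominal volumes so the
# planted activity mechanism is purely steric. Volumes are nominal per-group
# constants (A^3), not computed molecular volumes.
.DEFAULT_SUBSTITUENTS <- data.frame(
  name = c("H", "Me", "Et", "nPr", "iPr", "nBu", "tBu", "neoPent"),
  smiles = c("", "C", "CC", "CCC", "C(C)C", "CCCC", "C(C)(C)C", "CC(C)(C)C"),
  volume = c(7.2, 33.7, 50.8, 67.9, 66.8, 85.0, 84.0, 102.0),
  stringsAsFactors = FALSE
)

#' Specification of a synthetic congeneric series
#'
#' @param scaffold scaffold SMILES containing the attachment marker `({R})`
#'   (default: the 3,5-diphenyl-4,5-dihydropyrazole-1-carbothioamide scaffold
#'   with a para slot on the C5 phenyl).
#' @param substituents data.frame with columns `name`, `smiles` (branch
#'   fragment, empty string for H) and `volume` (nominal bulk in A^3);
#'   at least 6 rows.
#' @param slope activity change per A^3 of substituent volume (default 0.02,
#'   about two log units over the default volume range).
#' @param noise_sd Gaussian noise on the activity (default 0.1 log units).
#' @param seed integer seed.
#' @return a `series_spec` list.
#' @export
series_spec <- function(scaffold = "NC(=S)N1N=C(C2=CC=CC=C2)CC1C3=CC=C({R})C=C3",
                        substituents = .DEFAULT_SUBSTITUENTS,
                        slope = 0.02, noise_sd = 0.1, seed = 1L) {
  if (!grepl("({R})", scaffold, fixed = TRUE))
    stop("scaffold must contain the attachment marker ({R})")
  if (nrow(substituents) < 6) stop("need at least 6 substituents")
  if (!is.finite(slope)) stop("slope must be finite")
  structure(list(scaffold = scaffold, substituents = substituents,
                 slope = slope, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "series_spec")
}

#' Generate a synthetic congeneric series with known steric ground truth
#'
#' One compound per substituent; `activity = slope * volume + noise`. The
#' records feed the full pipeline (embedding, alignment, fields, PLS).
#'
#' @param spec a [series_spec()].
#' @return a `compound_table`-like data.frame with columns `id`, `role`,
#'   `smiles`, `volume`, `activity`, plus the spec as attribute `spec`.
#' @export
simulate_congeneric_series <- function(spec = series_spec()) {
  stopifnot(inherits(spec, "series_spec"))
  st <- spec$substituents
  smiles <- character(nrow(st))
  for (k in seq_len(nrow(st))) {
    smiles[k] <- if (nzchar(st$smiles[k]))
      gsub("{R}", st$smiles[k], spec$scaffold, fixed = TRUE)
    else gsub("({R})", "", spec$scaffold, fixed = TRUE)
    ok <- tryCatch({ parse_smiles(smiles[k]); TRUE }, error = function(e) FALSE)
    if (!ok)
      stop("substituent '", st$name[k], "' cannot be attached to the scaffold")
  }
  act <- with_seed(spec$seed,
                   spec$slope * st$volume + stats::rnorm(nrow(st), 0, spec$noise_sd))
  out <- data.frame(id = paste0("S", seq_len(nrow(st)), "_", st$name),
                    role = "train", smiles = smiles, volume = st$volume,
                    activity = act, stringsAsFactors = FALSE)
  attr(out, "spec") <- spec
  out
}
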