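# Leave-one-out cross-validation. Each compound is excluded and predicted
# exactly once; PRESS is the sum of squared prediction errors,
# q2 = 1 - PRESS/SS_total and SDEP = sqrt(PRESS/n). For a raw field table the
# whole preprocessing chain (minimum-sigma filtering and block scaling) is
# re-estimated inside every fold, so no information leaks from the excluded
# compound. SS_total is taken about the mean of the n-1 training responses of
# each fold by default ("fold"); the whole-sample convention is available as
# ss_total = "global".

#' Leave-one-out cross-validation of a PLS model
#'
#' @param X predictor matrix, or a raw `field_table` (preprocessing then runs
#'   inside each fold; see Details).
#' @param y response vector (compound order for a field table).
#' @param n_components latent variables per fold model.
#' @param ss_total `"fold"` (default) or `"global"` reference mean for the
#'   total sum of squares in q2.
#' @param min_sigma minimum-sigma threshold applied per fold (field tables
#'   only).
#' @return a `cv_result`: list with `predictions` (data.frame `id`,
#'   `observed`, `predicted`), `press`, `q2`, `sdep`, `n_components`.
#' @export
loo_cross_validate <- function(X, y, n_components, ss_total = c("fold", "global"),
                               min_sigma = 2.0) {
  ss_total <- match.arg(ss_total)
  n <- length(y)
  if (stats::var(y) == 0) stop("zero variance in y")
  is_table <- inherits(X, "field_table")
  if (!is_table) {
    X <- as.matrix(X)
    stopifnot(nrow(X) == n)
  } else stopifnot(nrow(X$X) == n)
  if (n < n_components + 3) stop("need n >= n_components + 3 for LOO")
  pred <- numeric(n)
  sstot <- 0
  for (i in seq_len(n)) {
    yi <- y[-i]
    if (stats::var(yi) == 0) stop("zero-variance y in fold ", i)
    if (is_table) {
      fold <- X
      fold$X <- X$X[-i, , drop = FALSE]
      fold <- filter_columns(fold, min_sigma)
      fold <- scale_comfa_std(fold)
      m <- fit_pls(scaled_matrix(fold), yi, n_components)
      held <- X
      held$X <- X$X[i, , drop = FALSE]
      held$mask <- fold$mask
      held$scaling <- fold$scaling
      pred[i] <- predict(m, scaled_matrix(held))
    } else {
      m <- fit_pls(X[-i, , drop = FALSE], yi, n_components)
      pred[i] <- predict(m, X[i, , drop = FALSE])
    }
    ref <- if (ss_total == "fold") mean(yi) else mean(y)
    sstot <- sstot + (y[i] - ref)^2
  }
  press <- sum((y - pred)^2)
  ids <- if (is_table) X$ids else rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  structure(list(
    predictions = data.frame(id = ids, observed = y, predicted = pred,
                             stringsAsFactors = FALSE),
    press = press, q2 = 1 - press / sstot, sdep = sqrt(press / n),
    n_components = n_components
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> LOO, %d components: PRESS = %.4f, q2 = %.4f, SDEP = %.4f\n",
              x$n_components, x$press, x$q2, x$sdep))
  invisible(x)
}

#' y-scrambling permutation null distribution of q2
#'
#' Standard QSAR response-permutation validation: the LOO q2 is recomputed for
#' `n_perm` seeded random permutations of y.
#'
#' @param X predictor matrix or raw `field_table`.
#' @param y response vector.
#' @param n_perm number of permutations (>= 10).
#' @param seed integer seed; permutation k uses the k-th draw of one stream.
#' @param n_components latent variables per model.
#' @param ... passed to [loo_cross_validate()].
#' @return list with `q2` (length `n_perm`) and `quantiles` (5/50/95%).
#' @export
permutation_null <- function(X, y, n_perm, seed, n_components = 2, ...) {
  if (n_perm < 10) stop("n_perm must be >= 10")
  if (stats::var(y) == 0) stop("zero variance in y")
  q2 <- numeric(n_perm)
  for (k in seq_len(n_perm)) {
    yp <- with_seed(seed + k, sample(y))
    q2[k] <- loo_cross_validate(X, yp, n_components, ...)$q2
  }
  list(q2 = q2,
       quantiles = stats::quantile(q2, c(0.05, 0.5, 0.95), names = TRUE))
}
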