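# NIPALS partial least squares for a univariate response. With a single y the
# weight vector of each component is exactly the X'y direction (no iteration
# and no random initialization), so fitting is fully deterministic. Scores are
# mutually orthogonal by construction; regression coefficients are reported on
# the scale of the matrix supplied (mapping back to raw energy units for a
# scaled field table is handled by field_contributions()/comfa helpers).

#' Fit a PLS regression by NIPALS
#'
#' @param X predictor matrix (n x p, finite entries).
#' @param y numeric response of length n.
#' @param n_components number of latent variables to extract.
#' @return a `pls_model`: list with `coefficients` (length p, on the scale of
#'   `X`), `intercept`, `weights`, `loadings`, `scores`, `y_loadings`,
#'   `x_center`, `y_center`, `n_components`, `n`, and the training row names
#'   as `ids`.
#' @export
fit_pls <- function(X, y, n_components) {
  X <- as.matrix(X)
  if (!is.numeric(X) || any(!is.finite(X))) stop("X must be finite numeric")
  if (length(y) != nrow(X)) stop("rows(X) must equal length(y)")
  if (any(!is.finite(y))) stop("y must be finite")
  n_components <- as.integer(n_components)
  if (n_components < 1) stop("n_components must be >= 1")
  if (nrow(X) < n_components + 2)
    stop("need at least n_components + 2 rows")
  xc <- colMeans(X); yc <- mean(y)
  E <- sweep(X, 2, xc); f <- y - yc
  p <- ncol(X)
  W <- matrix(0, p, n_components); P <- matrix(0, p, n_components)
  TT <- matrix(0, nrow(X), n_components); cvec <- numeric(n_components)
  x_ss0 <- sum(E^2)
  for (a in seq_len(n_components)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * max(1, sqrt(x_ss0)) || nw == 0)
      stop("n_components exceeds the effective rank of X (component ", a, ")")
    w <- w / nw
    t <- as.numeric(E %*% w)
    tt <- sum(t^2)
    if (tt < 1e-24) stop("n_components exceeds the effective rank of X (component ", a, ")")
    pvec <- as.numeric(crossprod(E, t)) / tt
    ca <- sum(t * f) / tt
    E <- E - tcrossprod(t, pvec)
    f <- f - ca * t
    W[, a] <- w; P[, a] <- pvec; TT[, a] <- t; cvec[a] <- ca
  }
  R <- W %*% solve(crossprod(P, W))
  beta <- as.numeric(R %*% cvec)
  structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    intercept = yc - sum(xc * beta),
    weights = W, loadings = P, scores = TT, y_loadings = cvec,
    x_center = xc, y_center = yc,
    n_components = n_components, n = nrow(X),
    ids = rownames(X)
  ), class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d components, %d training rows, %d predictors\n",
              x$n_components, x$n, length(x$coefficients)))
  invisible(x)
}

#' Predict from a fitted PLS model
#'
#' @param object a `pls_model`.
#' @param newdata matrix (or vector) of rows sharing the model's column layout.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, ncol = length(object$coefficients))
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coefficients))
    stop("layout mismatch: model expects ", length(object$coefficients),
         " columns, got ", ncol(newdata))
  as.numeric(newdata %*% object$coefficients) + object$intercept
}

#' Conventional (fitted) model statistics
#'
#' `r2 = 1 - RSS/SS_tot`, `SEE = sqrt(RSS/(n - c - 1))` and
#' `F = (r2/c) / ((1 - r2)/(n - c - 1))` with degrees of freedom
#' `(c, n - c - 1)` for `c` latent components.
#'
#' @param model a fitted `pls_model`.
#' @param X,y the training data the model was fitted on.
#' @return a `fit_stats` list: `r2`, `see`, `f_value`, `df` (length 2),
#'   `n`, `n_components`, `overflow` (`TRUE` for a perfect fit, where the
#'   F statistic is infinite).
#' @export
conventional_stats <- function(model, X, y) {
  stopifnot(inherits(model, "pls_model"))
  n <- length(y); cc <- model$n_components
  if (n <= cc + 1) stop("need n > n_components + 1 for conventional statistics")
  fitted <- predict(model, X)
  rss <- sum((y - fitted)^2)
  sstot <- sum((y - mean(y))^2)
  if (sstot <= 0) stop("zero variance in y")
  r2 <- 1 - rss / sstot
  see <- sqrt(rss / (n - cc - 1))
  overflow <- rss <= 1e-12 * sstot
  fval <- if (overflow) Inf else (r2 / cc) / ((1 - r2) / (n - cc - 1))
  structure(list(r2 = r2, see = see, f_value = fval, df = c(cc, n - cc - 1),
                 n = n, n_components = cc, overflow = overflow),
            class = "fit_stats")
}

#' @export
print.fit_stats <- function(x, ...) {
  cat(sprintf("r2 = %.4f, SEE = %.4f, F(%d, %d) = %.3f\n",
              x$r2, x$see, x$df[1], x$df[2], x$f_value))
  invisible(x)
}

#' Steric/electrostatic contribution fractions of a fitted model
#'
#' Contribution of field f is `sum_{j in f} |coef_j| * sd_j` over the unmasked
#' columns, with coefficients mapped back to raw energy units and sd taken on
#' the raw column scale, normalized so the two fractions sum to one.
#'
#' @param model a `pls_model` fitted on `scaled_matrix(table)`.
#' @param table the `field_table` the model was fitted on.
#' @return list with `steric_fraction` and `electrostatic_fraction`.
#' @export
field_contributions <- function(model, table) {
  stopifnot(inherits(model, "pls_model"), inherits(table, "field_table"))
  if (length(model$coefficients) != sum(table$mask))
    stop("model was not fitted on this table's unmasked columns")
  fld <- table$field[table$mask]
  coef_raw <- model$coefficients
  if (!is.null(table$scaling)) {
    for (f in names(table$scaling$block_scale)) {
      s <- table$scaling$block_scale[f]
      if (!is.na(s)) coef_raw[fld == f] <- coef_raw[fld == f] / s
    }
  }
  sd_raw <- apply(table$X[, table$mask, drop = FALSE], 2, stats::sd)
  contr <- vapply(c("steric", "electrostatic"), function(f)
    sum(abs(coef_raw[fld == f]) * sd_raw[fld == f]), numeric(1))
  tot <- sum(contr)
  if (tot <= 0) stop("zero total contribution")
  list(steric_fraction = unname(contr["steric"] / tot),
       electrostatic_fraction = unname(contr["electrostatic"] / tot))
}

#' Per-point coefficient x standard deviation values
#'
#' The raw-scale `coef_j * sd_j` map used for contouring.
#'
#' @inheritParams field_contributions
#' @return data.frame with columns `field`, `point`, `value`.
#' @export
coef_sd_map <- function(model, table) {
  stopifnot(inherits(model, "pls_model"), inherits(table, "field_table"))
  fld <- table$field[table$mask]
  coef_raw <- model$coefficients
  if (!is.null(table$scaling)) {
    for (f in names(table$scaling$block_scale)) {
      s <- table$scaling$block_scale[f]
      if (!is.na(s)) coef_raw[fld == f] <- coef_raw[fld == f] / s
    }
  }
  sd_raw <- apply(table$X[, table$mask, drop = FALSE], 2, stats::sd)
  data.frame(field = fld, point = table$point[table$mask],
             value = unname(coef_raw * sd_raw))
}

#' Choose the component count by leave-one-out q2
#'
#' Computes LOO q2 for 1..`max_components` latent variables and returns the
#' count maximizing q2, ties broken toward fewer components.
#'
#' @param X predictor matrix.
#' @param y response.
#' @param max_components largest count examined (>= 1).
#' @param ... passed to [loo_cross_validate()].
#' @return integer component count.
#' @export
select_components <- function(X, y, max_components, ...) {
  stopifnot(max_components >= 1)
  q2 <- vapply(seq_len(max_components), function(a)
    loo_cross_validate(X, y, a, ...)$q2, numeric(1))
  which.max(q2)  # which.max takes the first (smallest) index on ties
}
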