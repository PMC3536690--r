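test_that("a single noiseless column is fit exactly with one component", {
  x <- matrix(seq(-2, 2, length.out = 12), ncol = 1)
  m <- fit_pls(x, 2 * x[, 1], 1)
  expect_equal(unname(m$coefficients), 2, tolerance = 1e-12)
  expect_equal(m$intercept, 0, tolerance = 1e-12)
  expect_equal(conventional_stats(m, x, 2 * x[, 1])$r2, 1, tolerance = 1e-12)
})

test_that("full-rank PLS equals the least-squares oracle", {
  for (s in 1:3) {
    set.seed(s)
    X <- matrix(rnorm(60), 12, 5)
    y <- rnorm(12)
    m <- fit_pls(X, y, 5)
    ols <- as.numeric(cbind(1, X) %*% coef(lm(y ~ X)))
    expect_equal(predict(m, X), ols, tolerance = 1e-8)
  }
})

test_that("score vectors are mutually orthogonal", {
  set.seed(21)
  X <- matrix(rnorm(200), 20, 10); y <- rnorm(20)
  m <- fit_pls(X, y, 5)
  G <- crossprod(m$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
})

test_that("fitted r2 is non-decreasing in the component count", {
  set.seed(33)
  X <- matrix(rnorm(300), 20, 15); y <- rnorm(20)
  r2 <- vapply(1:6, function(a) {
    m <- fit_pls(X, y, a)
    conventional_stats(m, X, y)$r2
  }, numeric(1))
  expect_true(all(diff(r2) >= -1e-12))
})

test_that("rank overrun and bad inputs are rejected", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_pls(X, rnorm(10), 3), "rank")
  expect_error(fit_pls(X, rnorm(9), 1), "rows")
  Xb <- X; Xb[1, 1] <- NA
  expect_error(fit_pls(Xb, rnorm(10), 1), "finite")
})

test_that("conventional statistics follow the textbook formulas", {
  set.seed(5)
  X <- matrix(rnorm(30 * 8), 30, 8); y <- rnorm(30)
  m <- fit_pls(X, y, 6)
  st <- conventional_stats(m, X, y)
  expect_equal(st$df, c(6, 23))  # n = 30, 6 components
  fitted <- predict(m, X)
  rss <- sum((y - fitted)^2); sstot <- sum((y - mean(y))^2)
  expect_equal(st$r2, 1 - rss / sstot, tolerance = 1e-10)
  expect_equal(st$see, sqrt(rss / 23), tolerance = 1e-10)
  expect_equal(st$f_value, (st$r2 / 6) / ((1 - st$r2) / 23), tolerance = 1e-10)
  expect_error(conventional_stats(m, X[1:7, ], y[1:7]), "need n")  # n <= c + 1
  # perfect fit overflows the F statistic gracefully
  x1 <- matrix(seq_len(12), ncol = 1)
  mp <- fit_pls(x1, 3 * x1[, 1], 1)
  sp <- conventional_stats(mp, x1, 3 * x1[, 1])
  expect_true(sp$overflow)
  expect_identical(sp$f_value, Inf)
  expect_equal(sp$see, 0, tolerance = 1e-10)
})

test_that("field contributions respect symmetry and degenerate cases", {
  set.seed(8)
  A <- matrix(rnorm(40), 10, 4)
  # electrostatic block an exact duplicate of the steric block -> 0.5/0.5
  tab <- fake_field_table(cbind(A, A),
                          field = rep(c("steric", "electrostatic"), each = 4))
  tab <- scale_comfa_std(tab)
  m <- fit_pls(scaled_matrix(tab), rnorm(10), 2)
  fc <- field_contributions(m, tab)
  expect_equal(fc$steric_fraction, 0.5, tolerance = 1e-9)
  expect_equal(fc$steric_fraction + fc$electrostatic_fraction, 1,
               tolerance = 1e-9)

  # zero electrostatic signal: constant block carries no coefficient mass
  tab2 <- fake_field_table(cbind(A, matrix(0, 10, 4)),
                           field = rep(c("steric", "electrostatic"), each = 4))
  tab2 <- filter_columns(tab2, min_sigma = 0.001)
  tab2 <- scale_comfa_std(tab2)
  m2 <- fit_pls(scaled_matrix(tab2), A %*% c(1, 2, 0, 1), 2)
  fc2 <- field_contributions(m2, tab2)
  expect_equal(fc2$steric_fraction, 1)
  expect_equal(fc2$electrostatic_fraction, 0)
})

test_that("packaged-run contributions sum to one and are recorded", {
  fc <- packaged_run()$contributions
  expect_equal(fc$steric_fraction + fc$electrostatic_fraction, 1,
               tolerance = 1e-9)
  expect_gte(fc$steric_fraction, 0)
  expect_gte(fc$electrostatic_fraction, 0)
})

test_that("select_components maximizes LOO q2 with ties toward fewer", {
  expect_equal(select_components(matrix(rnorm(40), 20, 2), rnorm(20), 1), 1)
  # constructed 2-factor noiseless signal: X spans exactly the two factors
  set.seed(13)
  TT <- matrix(rnorm(40), 20, 2)
  X <- TT %*% matrix(c(1, 0, 1, 1, 0, 1, 2, -1, 0.5, 1, -1, 2), 2, 6)
  y <- TT %*% c(1, -2)
  expect_equal(select_components(X, as.numeric(y), 2), 2)
  # agrees with the direct argmax oracle on a noisy instance
  set.seed(14)
  Xn <- matrix(rnorm(20 * 6), 20, 6); yn <- rnorm(20)
  q2 <- vapply(1:4, function(a) loo_cross_validate(Xn, yn, a)$q2, numeric(1))
  expect_equal(select_components(Xn, yn, 4), which.max(q2))
})
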