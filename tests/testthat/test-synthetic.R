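test_that("field-dataset generator is a pure function of seed and parameters", {
  d1 <- simulate_field_dataset(12, 20, 4, 1.5, 0.3, seed = 9)
  d2 <- simulate_field_dataset(12, 20, 4, 1.5, 0.3, seed = 9)
  expect_identical(d1$X, d2$X); expect_identical(d1$y, d2$y)
  expect_identical(d1$signal_columns, d2$signal_columns)
  # the global RNG stream is left untouched
  set.seed(1); before <- .Random.seed
  invisible(simulate_field_dataset(12, 20, 4, 1, 0.1, seed = 2))
  expect_identical(.Random.seed, before)
  # planted linear model holds exactly at zero noise
  d0 <- simulate_field_dataset(12, 20, 4, 1.5, 0, seed = 9)
  expect_equal(d0$y, as.numeric(d0$X %*% d0$beta_true), tolerance = 1e-12)
  expect_true(all(d0$beta_true[-d0$signal_columns] == 0))
  expect_error(simulate_field_dataset(4, 20, 4, 1, 0, 1), "n >= 8")
  expect_error(simulate_field_dataset(12, 3, 4, 1, 0, 1), "k_signal")
})

test_that("noiseless single-column signal is recovered almost perfectly", {
  d <- simulate_field_dataset(40, 1, 1, 2, 0, seed = 31)  # n >> p_effective
  expect_gte(loo_cross_validate(d$X, d$y, 1)$q2, 0.999)
})

test_that("a null signal gives low q2 (median over 25 seeds)", {
  q2 <- vapply(1:25, function(s) {
    d <- simulate_field_dataset(16, 24, 4, 0, 1, seed = s)
    loo_cross_validate(d$X, d$y, 2)$q2
  }, numeric(1))
  expect_lte(median(q2), 0.2)
})

test_that("fitted coefficient mass concentrates on the signal columns", {
  wins <- vapply(1:20, function(s) {
    d <- simulate_field_dataset(40, 200, 10, 1, 0.1, seed = s)
    m <- fit_pls(d$X, d$y, 3)
    mass <- abs(m$coefficients)
    sig <- sum(mass[d$signal_columns])
    top_other <- sum(sort(mass[-d$signal_columns], decreasing = TRUE)[1:10])
    sig > top_other
  }, logical(1))
  expect_gte(mean(wins), 0.5)  # median over 20 seeds: signal block wins
})

test_that("congeneric series generator validates its inputs", {
  ser <- simulate_congeneric_series(series_spec(seed = 3))
  expect_equal(nrow(ser), 8)
  expect_true(all(ser$role == "train"))
  ser2 <- simulate_congeneric_series(series_spec(seed = 3))
  expect_identical(ser$activity, ser2$activity)
  subs <- data.frame(name = c("H", "Me", "Et", "nPr", "iPr", "bad"),
                     smiles = c("", "C", "CC", "CCC", "C(C)C", "C1C"),
                     volume = 1:6)
  expect_error(simulate_congeneric_series(series_spec(substituents = subs)),
               "substituent 'bad'")
  expect_error(series_spec(scaffold = "CCO"), "attachment marker")
  expect_error(series_spec(substituents = subs[1:3, ]), "at least 6")
})

test_that("the synthetic series passes through the whole 3D pipeline", {
  run <- synthetic_run()
  expect_equal(length(run$aligned), 8)  # all embeddable and alignable
  expect_true(all(attr(run$aligned, "alignment_report")$core_rmsd <= 0.8))
})

test_that("a purely steric planted mechanism yields a steric-dominated model", {
  run <- synthetic_run()  # noise 0, positive slope on substituent volume
  fc <- field_contributions(run$model, run$table)
  expect_gt(fc$steric_fraction, 0.5)
})

test_that("favored steric contours recover the planted substituent region", {
  run <- synthetic_run()
  ct <- contour_thresholds(run$model, run$table, c(80, 20))
  pts <- grid_points(run$grid)
  # substituent atoms of the bulkiest analog: heavy atoms far from every atom
  # of the aligned unsubstituted parent
  parent <- coords(run$aligned[[1]])
  big <- run$aligned[["S8_neoPent"]]
  bx <- coords(big)[big$atoms$element != "H", , drop = FALSE]
  dmin <- apply(bx, 1, function(p) min(sqrt(colSums((t(parent) - p)^2))))
  ctr <- colMeans(bx[dmin > 1.5, , drop = FALSE])
  fav <- ct$steric$favored_points
  d <- sqrt(colSums((t(pts[fav, , drop = FALSE]) - ctr)^2))
  expect_true(all(d <= 4))  # favored bulk region clusters at the substituent
})
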