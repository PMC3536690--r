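test_that("contour thresholds are nearest-rank percentiles of the coef*sd map", {
  run <- synthetic_run()
  ct <- contour_thresholds(run$model, run$table, c(80, 20))
  map <- coef_sd_map(run$model, run$table)
  for (f in c("steric", "electrostatic")) {
    v <- sort(map$value[map$field == f])
    n <- length(v)
    expect_equal(ct[[f]]$favored_threshold, v[ceiling(0.8 * n)])
    expect_equal(ct[[f]]$disfavored_threshold, v[n + 1 - ceiling(0.8 * n)])
  }
  expect_error(contour_thresholds(run$model, run$table, c(20, 80)),
               "must satisfy")
})

test_that("contour point sets are monotone in the level", {
  run <- synthetic_run()
  a <- contour_thresholds(run$model, run$table, c(80, 20))
  b <- contour_thresholds(run$model, run$table, c(90, 10))
  expect_true(all(b$steric$favored_points %in% a$steric$favored_points))
  expect_true(all(b$steric$disfavored_points %in% a$steric$disfavored_points))
})

test_that("symmetric coef*sd distributions give thresholds symmetric about 0", {
  # all columns share the same sd; a sign-symmetric coefficient vector then
  # yields a sign-symmetric coef*sd map
  p <- 100
  tab <- fake_field_table(rbind(rep(1, p), rep(-1, p)),
                          field = rep(c("steric", "electrostatic"), each = p / 2))
  model <- structure(list(coefficients = c(-(1:25), 1:25, -(1:25), 1:25) / 10,
                          n_components = 1), class = "pls_model")
  ct <- contour_thresholds(model, tab, c(80, 20))
  for (f in c("steric", "electrostatic")) {
    expect_equal(ct[[f]]$favored_threshold, -ct[[f]]$disfavored_threshold,
                 tolerance = 1e-9)
  }
  # brute-force percentile oracle on the 1..n sequence
  mseq <- structure(list(coefficients = rep(1, p), n_components = 1),
                    class = "pls_model")
  tab2 <- fake_field_table(rbind(1:p, -(1:p)) / sqrt(2),
                           field = rep(c("steric", "electrostatic"), each = p / 2))
  ct2 <- contour_thresholds(mseq, tab2, c(80, 20))
  v <- sort(apply(tab2$X[, 1:(p / 2)], 2, sd))
  n <- p / 2
  expect_equal(ct2$steric$favored_threshold, v[ceiling(0.8 * n)],
               tolerance = 1e-12)
  expect_equal(ct2$steric$disfavored_threshold, v[n + 1 - ceiling(0.8 * n)],
               tolerance = 1e-12)
})

test_that("grid export round-trips values through both formats", {
  g <- grid_spec(c(-4, -4, -4), 2, c(5, 5, 5))
  vals <- sin(seq_len(125))
  for (fmt in c("cube", "dx")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    export_grid(vals, g, fmt, f)
    back <- read_grid(f, fmt)
    expect_identical(back$values, vals)
    expect_equal(back$grid$counts, g$counts)
    expect_equal(back$grid$origin, g$origin, tolerance = 1e-9)
  }
  f <- withr::local_tempfile(fileext = ".cube")
  export_grid(vals, g, "cube", f)
  expect_match(readLines(f)[4], "^    5 ")  # nx = 5 in the header
  expect_error(export_grid(vals[-1], g, "cube", f), "does not match")
})

test_that("prediction records use the observed - predicted convention", {
  run <- synthetic_run()
  y <- run$series$activity
  names(y) <- run$series$id
  rec <- predict_records(run$model, run$table, observed = y)
  expect_equal(rec$residual, rec$observed - rec$predicted, tolerance = 1e-12)
  # training rows through their own model equal the fitted values
  fitted <- predict(run$model, scaled_matrix(run$table))
  expect_equal(rec$predicted, fitted, tolerance = 1e-10)
  # rows given without observations carry NA residuals
  rec2 <- predict_records(run$model, run$table)
  expect_true(all(is.na(rec2$residual)))
})

test_that("a centered zero row predicts the intercept", {
  set.seed(6)
  X <- matrix(rnorm(40), 10, 4)
  m <- fit_pls(X, rnorm(10), 2)
  expect_equal(predict(m, rep(0, 4)), m$intercept, tolerance = 1e-12)
  expect_error(predict(m, matrix(0, 1, 3)), "layout mismatch")
})

test_that("external validation statistics match the direct formulas", {
  rec <- data.frame(observed = c(1, 2, 3, 4), predicted = c(1, 2, 3, 4))
  st <- external_validation_stats(rec, n_components = 1)
  expect_equal(st$r2, 1)
  expect_equal(st$see, 0)
  set.seed(7)
  obs <- rnorm(16); prd <- rnorm(16)
  st2 <- external_validation_stats(data.frame(observed = obs, predicted = prd),
                                  n_components = 6)
  expect_equal(st2$r2, cor(obs, prd)^2, tolerance = 1e-10)
  expect_equal(st2$see, sqrt(sum((obs - prd)^2) / (16 - 6 - 1)),
               tolerance = 1e-10)
  expect_error(external_validation_stats(
    data.frame(observed = obs, predicted = rep(1, 16)), 6), "constant")
  expect_error(external_validation_stats(
    data.frame(observed = obs[1:2], predicted = prd[1:2]), 1), "at least 3")
})

test_that("the report bundle is complete and byte-stable", {
  run <- packaged_run()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_report(run, d1)
  files <- c("report.json", "training_predictions.csv", "test_predictions.csv",
             "contours_steric.cube", "contours_electrostatic.cube",
             "alignment.sdf", "alignment_report.csv")
  expect_true(all(file.exists(file.path(d1, files))))
  expect_equal(nrow(read.csv(file.path(d1, "training_predictions.csv"))), 30)
  expect_equal(nrow(read.csv(file.path(d1, "test_predictions.csv"))), 16)
  write_report(run, d2)
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))
  broken <- run; broken$model <- NULL
  expect_error(write_report(broken, d1), "missing stage output.*model")
})
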