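test_that("build_grid spans min - margin to max + margin", {
  one <- single_atom_mol(pos = c(0, 0, 0))
  g <- build_grid(one, spacing = 2, margin = 4)
  expect_equal(g$counts, c(5L, 5L, 5L))
  expect_equal(n_grid_points(g), 125)
  expect_equal(g$origin, c(-4, -4, -4))

  g0 <- build_grid(one, spacing = 2, margin = 0)
  expect_equal(g0$counts, c(1L, 1L, 1L))

  two <- list(single_atom_mol(pos = c(0, 0, 0), id = "a"),
              single_atom_mol(pos = c(2, 0, 0), id = "b"))
  g2 <- build_grid(two, spacing = 2, margin = 4)
  expect_equal(g2$counts, c(6L, 5L, 5L))

  expect_error(build_grid(list()), "empty")
})

test_that("steric energy follows the truncated Lennard-Jones closed form", {
  mol <- single_atom_mol()             # carbon: r 1.70, eps 0.107
  probe <- probe_spec()                # r 1.52, eps 0.107
  R <- 1.70 + 1.52
  eps <- sqrt(0.107 * 0.107)
  expect_lt(abs(steric_energy_at(c(50, 0, 0), mol, probe)), 1e-6)
  expect_equal(steric_energy_at(c(R, 0, 0), mol, probe), -eps, tolerance = 1e-12)
  expect_equal(steric_energy_at(c(0, 0, 0), mol, probe), 30)  # truncation
  # monotone increase as r shrinks below the minimum
  r <- seq(R, 0.3, length.out = 40)
  e <- steric_energy_at(cbind(r, 0, 0), mol, probe)
  expect_true(all(diff(e) >= 0))
})

test_that("electrostatic energy follows the clipped r^-2 Coulomb form", {
  probe <- probe_spec()
  neutral <- single_atom_mol(charge = 0)
  expect_equal(electrostatic_energy_at(c(2, 0, 0), neutral, probe), 0)
  q <- single_atom_mol(charge = 0.25)
  expect_equal(electrostatic_energy_at(c(2, 0, 0), q, probe),
               332.0 * 0.25 / 4, tolerance = 1e-12)  # 20.75
  unit <- single_atom_mol(charge = 1)
  expect_equal(electrostatic_energy_at(c(1, 0, 0), unit, probe), 30)  # clip
  expect_equal(electrostatic_energy_at(c(1, 0, 0),
                                       single_atom_mol(charge = -1), probe), -30)
})

test_that("field table has the normative shape and matches a loop oracle", {
  mol <- single_atom_mol(pos = c(0.3, -0.2, 0.1), charge = 0.2)
  grid <- build_grid(mol, spacing = 2, margin = 4)
  tab <- compute_field_table(list(mol, mol), grid,
                             exclude_electrostatics = FALSE)
  expect_equal(dim(tab$X), c(2, 2 * n_grid_points(grid)))
  expect_equal(tab$X[1, ], tab$X[2, ])  # duplicate molecules, identical rows

  # brute-force per-point oracle, raster order with k fastest
  pts <- grid_points(grid)
  probe <- probe_spec()
  R <- 1.70 + probe$radius; eps <- sqrt(0.107 * probe$epsilon)
  for (p in seq_len(nrow(pts))) {
    r <- sqrt(sum((pts[p, ] - c(0.3, -0.2, 0.1))^2))
    es <- min(eps * ((R / r)^12 - 2 * (R / r)^6), 30)
    ee <- min(max(332 * 0.2 / r^2, -30), 30)
    expect_equal(unname(tab$X[1, p]), es, tolerance = 1e-10 * max(1, abs(es)))
    expect_equal(unname(tab$X[1, n_grid_points(grid) + p]), ee,
                 tolerance = 1e-10 * max(1, abs(ee)))
  }
  expect_error(compute_field_table(single_atom_mol(pos = c(99, 0, 0)), grid),
               "outside the grid hull")
})

test_that("fields are invariant under joint translation of system and grid", {
  mol <- single_atom_mol(pos = c(0.5, 0.5, 0.5), charge = 0.3)
  g1 <- build_grid(mol, spacing = 2, margin = 4)
  t1 <- compute_field_table(mol, g1)
  shift <- c(3.1, -2.2, 7.9)
  mol2 <- mol
  mol2$atoms$x <- mol$atoms$x + shift[1]
  mol2$atoms$y <- mol$atoms$y + shift[2]
  mol2$atoms$z <- mol$atoms$z + shift[3]
  g2 <- grid_spec(g1$origin + shift, g1$spacing, g1$counts)
  t2 <- compute_field_table(mol2, g2)
  expect_equal(t1$X, t2$X, tolerance = 1e-9)
})

test_that("sterically excluded points get the mean-electrostatic convention", {
  m1 <- single_atom_mol(pos = c(0, 0, 0), charge = 0.5, id = "a")
  m2 <- single_atom_mol(pos = c(2, 0, 0), charge = -0.5, id = "b")
  grid <- grid_spec(c(0, 0, 0), 2, c(2, 1, 1))  # points at both atom centers
  tab <- compute_field_table(list(m1, m2), grid)
  np <- 2
  # point 1 sits on atom a: steric truncated for a, so its electrostatic value
  # is replaced by the value of b at that point
  expect_equal(unname(tab$X[1, 1]), 30)
  expect_equal(unname(tab$X[1, np + 1]), unname(tab$X[2, np + 1]))
  raw <- compute_field_table(list(m1, m2), grid, exclude_electrostatics = FALSE)
  expect_equal(unname(raw$X[1, np + 1]), 30)  # without the convention: clipped in-core value
})

test_that("column filtering masks by standard deviation", {
  X <- rbind(c(1, 5, 0, 2), c(1, -5, 0, -2), c(1, 5, 0, 2), c(1, -5, 0, -2))
  tab <- fake_field_table(X, field = rep(c("steric", "electrostatic"), each = 2))
  f <- filter_columns(tab, min_sigma = 2)
  expect_equal(f$mask, apply(X, 2, sd) >= 2)  # direct sd oracle
  expect_false(f$mask[1])                     # constant column masked
  expect_true(all(filter_columns(tab, min_sigma = 0)$mask))
  expect_error(filter_columns(tab, min_sigma = 100), "no variance above")
})

test_that("block scaling equalizes field variances and inverts exactly", {
  set.seed(11)
  X <- cbind(matrix(rnorm(40, sd = 6), 10, 4), matrix(rnorm(40, sd = 0.5), 10, 4))
  tab <- fake_field_table(X, field = rep(c("steric", "electrostatic"), each = 4))
  tab <- scale_comfa_std(filter_columns(tab, min_sigma = 0))
  S <- scaled_matrix(tab)
  v <- apply(S, 2, var)
  fld <- tab$field[tab$mask]
  expect_equal(sum(v[fld == "steric"]), sum(v[fld == "electrostatic"]),
               tolerance = 1e-9)
  expect_equal(unscale_matrix(tab), X[, tab$mask], tolerance = 1e-9,
               ignore_attr = TRUE)

  # one-block limit: scaling reduces to centering + division by the block sd
  tabs <- fake_field_table(X[, 1:4], field = rep("steric", 4),
                           point = 1:4)
  tabs$field <- rep("steric", 4); tabs$point <- 1:4
  tabs <- scale_comfa_std(tabs)
  manual <- sweep(X[, 1:4], 2, colMeans(X[, 1:4])) /
    sqrt(sum(apply(X[, 1:4], 2, var)))
  expect_equal(scaled_matrix(tabs), manual, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("truncation bounds hold on the packaged 46-compound run", {
  tab <- packaged_run()$table
  st <- tab$X[, tab$field == "steric"]
  el <- tab$X[, tab$field == "electrostatic"]
  expect_true(all(st <= 30 + 1e-12))
  expect_true(all(el >= -30 - 1e-12 & el <= 30 + 1e-12))
})
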