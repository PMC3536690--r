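test_that("embedding is deterministic and geometrically sane", {
  tab <- data.frame(id = "e", smiles = "CC")
  m1 <- embed_series(tab, seed = 123)[[1]]
  m2 <- embed_series(tab, seed = 123)[[1]]
  expect_identical(coords(m1), coords(m2))
  cc <- sqrt(sum((coords(m1)[1, ] - coords(m1)[2, ])^2))
  expect_gt(cc, 1.45); expect_lt(cc, 1.60)
  expect_error(embed_3d("C1CC"), "embedding failed|unparsable")
})

test_that("embedded molecules satisfy the structural invariants", {
  for (mol in packaged_aligned()[c("D5", "F7")]) {
    expect_equal(sum(mol$atoms$charge), 0, tolerance = 1e-3)
    xyz <- coords(mol)
    d <- sqrt(rowSums((xyz[mol$bonds$i, ] - xyz[mol$bonds$j, ])^2))
    expect_true(all(d >= 0.7 & d <= 2.2))
  }
})

test_that("find_core locates the dihydropyrazole core deterministically", {
  match <- find_core(packaged_aligned()[["D5"]])
  expect_equal(nrow(match), 8)  # ring + 3 attachment atoms
  expect_equal(length(unique(match$atom)), 8)
  expect_error(find_core(toy_mols()[["benzene"]]), "core absent")
  # the pattern matches itself by the identity mapping
  self <- find_core(parse_smiles("CN1N=C(C)CC1C"), "CN1N=C(C)CC1C")
  expect_equal(self$atom, 1:8)
})

test_that("kabsch_superpose recovers rigid transforms", {
  set.seed(4)
  P <- matrix(rnorm(30), 10, 3)
  id <- kabsch_superpose(P, P)
  expect_equal(id$rmsd, 0, tolerance = 1e-12)
  expect_equal(id$rotation, diag(3), tolerance = 1e-9)

  Rz <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))  # 90 degrees about z
  Q <- sweep(P %*% t(Rz), 2, c(1, 2, 3), "+")
  fit <- kabsch_superpose(P, Q)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$rotation, Rz, tolerance = 1e-9)
  expect_equal(fit$translation, c(1, 2, 3), tolerance = 1e-9)
})

test_that("reflections are disallowed: a chiral mirror image keeps rmsd > 0", {
  P <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  M <- P; M[, 3] <- -M[, 3]
  expect_gt(kabsch_superpose(M, P)$rmsd, 0.1)
})

test_that("superposition rmsd is invariant under pre-applied rigid motions", {
  set.seed(9)
  P <- matrix(rnorm(24), 8, 3)
  Q <- matrix(rnorm(24), 8, 3)
  base <- kabsch_superpose(P, Q)$rmsd
  for (s in 1:5) {
    set.seed(s)
    A <- matrix(rnorm(9), 3, 3)
    R <- qr.Q(qr(A))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    P2 <- sweep(P %*% t(R), 2, rnorm(3), "+")
    expect_equal(kabsch_superpose(P2, Q)$rmsd, base, tolerance = 1e-9)
  }
})

test_that("degenerate geometries are rejected", {
  expect_error(kabsch_superpose(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)),
               "at least 3")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_superpose(line, line + 1), "collinear")
})

test_that("align_series fixes the template, fits the core and is idempotent", {
  aligned <- packaged_aligned()
  rep <- attr(aligned, "alignment_report")
  expect_equal(rep$core_rmsd[rep$id == "D5"], 0)
  expect_true(all(rep$core_rmsd <= 0.8))  # every compound fits the shared core
  # realigning an aligned series changes nothing
  re <- align_series(aligned, "D5")
  dmax <- max(vapply(names(aligned), function(id)
    max(abs(coords(re[[id]]) - coords(aligned[[id]]))), numeric(1)))
  expect_lt(dmax, 1e-6)
  expect_error(align_series(aligned, "NOPE"), "not present")
  expect_error(align_series(c(aligned[1:2], toy_mols()["benzene"]), "D1"),
               "core absent.*benzene")
})
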