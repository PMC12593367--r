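# crystal with explicitly set per-copy torsions in a huge cell
torsion_crystal <- function(angles, label = "t") {
  mol <- make_molecule("asymmetric_chain4")
  coords <- NULL
  for (k in seq_along(angles)) {
    cc <- set_torsion(mol$coords, 1:4, angles[k])
    coords <- rbind(coords, sweep(cc, 2, c(20 * k, 0, 0), "+"))
  }
  x <- crystal(diag(100, 3), coords, rep(mol$elements, length(angles)),
               label = label)
  partition_molecules(x, mol)
}

test_that("torsion classes follow the absolute-angle threshold rule", {
  s180 <- torsion_crystal(180)
  s0 <- torsion_crystal(5)   # near-planar cis
  expect_equal(as.integer(torsion_class(list(s180, s0), 1:4)), c(1L, 0L))
  # Z' = 2 averaging: +100 and +80 average to 90, class 1 by the >= rule
  s_avg <- torsion_crystal(c(100, 80))
  tc <- torsion_class(list(s_avg), 1:4)
  expect_equal(attr(tc, "torsion"), 90, tolerance = 1e-8)
  expect_equal(as.integer(tc), 1L)
  # negative angles classify by magnitude
  expect_equal(as.integer(torsion_class(list(torsion_crystal(-150)), 1:4)),
               1L)
})

test_that("degenerate dihedrals raise an undefined-angle error", {
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0)),
               "undefined-angle")
})

test_that("density regression recovers planted linear relationships", {
  set.seed(8)
  coords <- matrix(rnorm(300 * 6), 300, 6)
  pc <- fake_kpca(coords)
  dens <- 1 + 0.1 * coords[, 3]
  res <- density_r2(pc, dens)
  expect_equal(res$component, 3L)
  expect_equal(res$r2, 1, tolerance = 1e-10)
  # independent noise: no component should appear strongly correlated
  pc500 <- fake_kpca(matrix(rnorm(500 * 32), 500, 32))
  res_null <- density_r2(pc500, rnorm(500))
  expect_lt(res_null$r2, 0.1)
  expect_error(density_r2(pc, rep(1, 300)), "constant density")
})

test_that("SVC recovers separable classes and fails on single-class input", {
  set.seed(21)
  n <- 120
  coords <- matrix(rnorm(n * 6), n, 6)
  labels <- as.integer(coords[, 1] > 0)
  pc <- fake_kpca(coords)
  res <- svc_accuracy(pc, labels, "single_best_of_32")
  expect_equal(res$balanced_accuracy, 1, tolerance = 0.02)
  expect_equal(res$features[[1]], 1)
  expect_error(svc_accuracy(pc, rep(1L, n), "single_best_of_32"),
               "both classes")
})

test_that("a planted two-descriptor separation needs the subset search", {
  set.seed(31)
  n <- 160
  coords <- matrix(rnorm(n * 5), n, 5)
  # separation along the x1 + x2 diagonal: neither component separates alone
  labels <- as.integer(coords[, 1] + coords[, 2] > 0)
  pc <- fake_kpca(coords)
  single <- svc_accuracy(pc, labels, "single_best_of_32")
  subset <- svc_accuracy(pc, labels, "best_subset_of_top5")
  expect_gt(subset$balanced_accuracy, single$balanced_accuracy)
  expect_gt(subset$balanced_accuracy, 0.95)
  expect_lt(single$balanced_accuracy, 0.9)
})

test_that("balanced accuracy sits at chance under label permutation", {
  set.seed(44)
  n <- 80
  pc <- fake_kpca(matrix(rnorm(n), n, 1))
  labels <- rep(c(0L, 1L), each = n / 2)
  accs <- vapply(1:100, function(i) {
    svc_accuracy(pc, sample(labels), "single_best_of_32",
                 C_grid = 1)$balanced_accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("SVC accuracy is invariant to component sign flips", {
  set.seed(9)
  coords <- matrix(rnorm(100 * 5), 100, 5)
  labels <- as.integer(coords[, 2] > 0.2)
  pc <- fake_kpca(coords)
  pcf <- fake_kpca(coords %*% diag(c(-1, 1, -1, 1, -1)))
  a1 <- svc_accuracy(pc, labels, "single_best_of_32", C_grid = 1)
  a2 <- svc_accuracy(pcf, labels, "single_best_of_32", C_grid = 1)
  expect_equal(a1$balanced_accuracy, a2$balanced_accuracy, tolerance = 1e-8)
})

test_that("geometric hydrogen-bond detection separates bonded from isolated", {
  mol <- make_molecule("symmetric_AB2")
  # donor water with one O-H bond aimed straight at the acceptor oxygen:
  # H...A = 1.9 A, D-H...A = 180 deg
  donor <- rbind(c(0, -2.86, 0),      # O (donor)
                 c(0, -1.90, 0),      # H on the line to the acceptor
                 c(0.757, -3.45, 0))  # second H
  bonded <- partition_molecules(
    crystal(diag(50, 3), rbind(mol$coords, donor),
            rep(mol$elements, 2), label = "hb"), mol)
  far <- partition_molecules(
    crystal(diag(50, 3),
            rbind(mol$coords, sweep(mol$coords, 2, c(20, 0, 0), "+")),
            rep(mol$elements, 2), label = "far"), mol)
  cls <- hbond_class(list(bonded, far), acceptor = 1, mol = mol)
  expect_equal(as.integer(cls), c(1L, 0L))
})
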