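test_that("kPCA of the identity kernel has the closed-form spectrum", {
  K <- structure(diag(3), labels = c("a", "b", "c"),
                 class = c("kernel_matrix", "matrix", "array"))
  pc <- kpca(K)
  # double-centering I(3) gives I - J/3: the 1-vector is annihilated and
  # every direction orthogonal to it keeps eigenvalue 1
  expect_equal(sort(pc$eigenvalues, decreasing = TRUE)[1:2],
               rep(1, 2), tolerance = 1e-10)
  expect_lt(pc$eigenvalues[3], 1e-10)
  dmat <- as.matrix(dist(pc$coords))
  off <- dmat[upper.tri(dmat)]
  expect_lt(diff(range(off)), 1e-10)  # equilateral configuration
})

test_that("descriptor Gram matrix reproduces the centered kernel", {
  K <- tri_kernel("adapted")
  pc <- kpca(K)
  n <- nrow(unclass(K))
  Km <- unclass(K)
  Kc <- Km - outer(rowMeans(Km), rep(1, n)) -
    outer(rep(1, n), rowMeans(Km)) + mean(Km)
  expect_lt(max(abs(tcrossprod(pc$coords) - Kc)), 1e-8)
  # duplicated structures land on identical coordinates
  envs <- tri_envs()[c(1, 1, 2, 3)]
  Kd <- normalize_kernel(build_kernel_matrix(envs, "adapted",
                                             mset = tri_mset()))
  pcd <- kpca(Kd)
  expect_lt(max(abs(pcd$coords[1, ] - pcd$coords[2, ])), 1e-6)
})

test_that("kPCA rejects indefinite kernels", {
  K <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(kpca(K), "kernel-integrity")
})

test_that("one-dimensional hulls recover textbook dressed energies", {
  h <- build_hull(matrix(c(0, 1, 2)), c(0, 1, 0))
  expect_equal(h$dressed_energy, c(0, 1, 0))
  expect_setequal(h$vertices, c(1L, 3L))
  expect_true(all(h$dressed_energy >= 0))
  expect_equal(h$dressed_energy[which.min(h$energies)], 0)
})

test_that("dressed energies match the exhaustive envelope oracle", {
  set.seed(77)
  for (case in 1:40) {
    d <- sample(1:2, 1)
    n <- sample((d + 3):18, 1)
    coords <- matrix(runif(n * d, -2, 2), n, d)
    energies <- runif(n, 0, 10)
    h <- build_hull(coords, energies)
    oracle <- pmax(energies - min(energies) -
                     envelope_oracle(coords, energies - min(energies)), 0)
    expect_lt(max(abs(h$dressed_energy - oracle)), 1e-8)
    expect_equal(h$dressed_energy[which.min(energies)], 0)
  }
})

test_that("degenerate descriptor geometry falls back to a subspace", {
  coords <- cbind(seq(0, 1, length.out = 8), rep(0.5, 8))
  expect_warning(h <- build_hull(coords, runif(8)), "degenerate")
  expect_true(all(h$dressed_energy >= 0))
  # fully constant descriptor: everything collapses to the energy minimum
  expect_warning(h0 <- build_hull(matrix(1, 8, 1), c(3, 1, 5, 2, 8, 1, 4, 6)),
                 "degenerate")
  expect_equal(h0$dressed_energy, c(3, 1, 5, 2, 8, 1, 4, 6) - 1)
})

test_that("candidate pools follow the smallest-window rule", {
  set.seed(5)
  coords <- matrix(rnorm(40), 20, 2)
  energies <- runif(20, 0, 20)
  h <- build_hull(coords, energies, labels = sprintf("s%02d", 1:20))
  known <- sprintf("s%02d", c(3, 11, 17))
  pool <- candidate_pool_from_known(h, known)
  window <- max(h$dressed_energy[c(3, 11, 17)])
  expect_equal(pool$window, window)
  expect_setequal(pool$members,
                  h$labels[h$dressed_energy <= window + 1e-12])
  # known = everything -> pool = everything
  expect_equal(candidate_pool_from_known(h, h$labels)$size, 20)
  # known = a hull vertex -> window 0, pool = all dressed-zero structures
  v <- h$labels[h$vertices[1]]
  pv <- candidate_pool_from_known(h, v)
  expect_equal(pv$window, 0)
  expect_setequal(pv$members, h$labels[h$dressed_energy == 0])
  expect_error(candidate_pool_from_known(h, character(0)), "empty")
  # monotone in window at fixed d
  sizes <- vapply(seq(0, max(h$dressed_energy), length.out = 12),
                  function(w) sum(h$dressed_energy <= w + 1e-12), integer(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("baseline pools behave like their defining constructions", {
  energies <- c(0, 2, 5, 9, 14, 25)
  labels <- letters[1:6]
  dens <- c(1.3, 1.25, 1.2, 1.1, 1.0, 0.8)
  # known = global minimum only: zero-width energy window
  b <- baseline_pools(energies, "a", labels, densities = dens)
  expect_equal(b$energy_cutoff$window, 0)
  expect_equal(b$energy_cutoff$size, 1)
  # constant density: degenerate hull handled
  expect_warning(
    b2 <- baseline_pools(energies, "a", labels, densities = rep(1, 6)),
    "degenerate")
  expect_equal(b2$energy_density$size, 1)
  # planted porous 'known' polymorph: low density, high energy, on the
  # energy-density hull edge; the density baseline isolates it while the
  # energy cutoff must drag in everything below it
  b3 <- baseline_pools(energies, c("a", "f"), labels, densities = dens)
  expect_equal(b3$energy_cutoff$size, 6)
  expect_lt(b3$energy_density$size, b3$energy_cutoff$size)
  # missing densities: hull baseline skipped with a warning
  expect_warning(b4 <- baseline_pools(energies, "a", labels, densities = NULL),
                 "skipping")
  expect_null(b4$energy_density)
})

test_that("noise resampling is reproducible and honours noise_sd = 0", {
  K <- tri_kernel("adapted")
  land <- tri_landscape()
  known <- land$labels[which.min(land$energies)]
  e0 <- resample_pools(K, land$energies, known, noise_sd = 0,
                       iterations = 12, seed = 3, d = 2)
  expect_equal(length(unique(e0$pool_sizes)), 1L)
  h <- build_hull(kpca(K)$coords[, 1:2], land$energies, labels = land$labels)
  expect_equal(e0$pool_sizes[1], candidate_pool_from_known(h, known)$size)
  e1 <- resample_pools(K, land$energies, known, noise_sd = 0.8,
                       iterations = 25, seed = 11, d = 2)
  e2 <- resample_pools(K, land$energies, known, noise_sd = 0.8,
                       iterations = 25, seed = 11, d = 2)
  expect_identical(e1$pool_sizes, e2$pool_sizes)
  e3 <- resample_pools(K, land$energies, known, noise_sd = 0.8,
                       iterations = 25, seed = 12, d = 2)
  expect_false(identical(e1$pool_sizes, e3$pool_sizes))
})

test_that("ensemble comparison follows Mann-Whitney arithmetic", {
  same <- compare_ensembles(rep(c(4, 5, 6), 20), rep(c(4, 5, 6), 20))
  expect_equal(same$p_value, 1, tolerance = 1e-12)
  sep <- compare_ensembles(1:250, 251:500)
  expect_lt(sep$p_value, 1e-10)
  set.seed(1)
  x <- sample(1:50, 30, replace = TRUE); y <- sample(3:60, 30, replace = TRUE)
  expect_equal(compare_ensembles(x, y)$p_value,
               compare_ensembles(sample(x), y)$p_value)
  expect_error(compare_ensembles(numeric(0), y), "nonempty")
})

test_that("rank correlation reproduces Kendall arithmetic", {
  h <- fake_hull(dressed = c(0, 1, 2, 3, 4), energies = c(0, 1, 2, 3, 4))
  expect_equal(rank_correlation(h, h$labels)$tau, 1)
  h2 <- fake_hull(dressed = c(4, 3, 2, 1, 0), energies = c(0, 1, 2, 3, 4))
  expect_equal(rank_correlation(h2, h2$labels)$tau, -1)
  # one adjacent transposition among 5: tau = 1 - 2 * 1 / 10
  h3 <- fake_hull(dressed = c(0, 2, 1, 3, 4), energies = c(0, 1, 2, 3, 4))
  expect_equal(rank_correlation(h3, h3$labels)$tau, 0.8)
  expect_error(rank_correlation(h3, h3$labels[1:2]), "at least 3")
})

test_that("downstream results are invariant to kPCA sign flips", {
  K <- tri_kernel("adapted")
  land <- tri_landscape()
  pc <- kpca(K)
  flipped <- pc
  flipped$coords <- pc$coords %*% diag((-1)^(seq_len(ncol(pc$coords))))
  h1 <- build_hull(pc$coords[, 1:2], land$energies, labels = land$labels)
  h2 <- build_hull(flipped$coords[, 1:2], land$energies, labels = land$labels)
  expect_lt(max(abs(h1$dressed_energy - h2$dressed_energy)), 1e-8)
  expect_equal(density_r2(pc, land$densities)$r2,
               density_r2(flipped, land$densities)$r2, tolerance = 1e-10)
})
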