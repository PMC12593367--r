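test_that("average kernel equals the brute-force mean over atom pairs", {
  envs <- tri_envs()
  for (pair in list(c(1, 2), c(3, 7), c(4, 4))) {
    expect_equal(average_pair(envs[[pair[1]]], envs[[pair[2]]]),
                 brute_force_average(envs[[pair[1]]], envs[[pair[2]]]),
                 tolerance = 1e-12)
  }
  # hand-set spectra, 2 atoms per structure: explicit 4-pair enumeration
  ea <- fake_env(rbind(c(1, 0), c(0, 2)), n_index = 2)
  eb <- fake_env(rbind(c(3, 1), c(2, 2)), n_index = 2)
  expect_equal(average_pair(ea, eb), (3 + 2 + 2 + 4) / 4)
})

test_that("C1 adapted kernel reduces to the same-index mean", {
  envs <- tri_envs()
  mset <- tri_mset()
  expect_equal(mset$Q, 1L)
  e1 <- envs[[2]]; e2 <- envs[[9]]
  direct <- mean(vapply(1:3, function(i)
    local_kernel(e1$spectra[i, ], e2$spectra[i, ]), numeric(1)))
  expect_equal(adapted_pair(e1, e2, mset), direct, tolerance = 1e-12)
})

test_that("single-atom molecules make adapted and average coincide", {
  ea <- fake_env(rbind(c(1.5, -2, 0.5)), n_index = 1)
  eb <- fake_env(rbind(c(0.25, 4, 1)), n_index = 1)
  ident <- structure(list(perms = list(1L), labels = "E", Q = 1L),
                     class = "mapping_set")
  expect_identical(adapted_pair(ea, eb, ident), average_pair(ea, eb))
})

test_that("swap-symmetric molecules match explicit two-mapping enumeration", {
  envs <- ab2_envs()
  mset <- find_mappings(make_molecule("symmetric_AB2"))
  expect_equal(mset$Q, 2L)
  for (pair in list(c(1, 2), c(3, 5))) {
    expect_equal(adapted_pair(envs[[pair[1]]], envs[[pair[2]]], mset),
                 brute_force_adapted(envs[[pair[1]]], envs[[pair[2]]], mset),
                 tolerance = 1e-12)
  }
})

test_that("adapted kernel is symmetric and invariant to group relabelling", {
  envs <- ab2_envs()
  mset <- find_mappings(make_molecule("symmetric_AB2"))
  k_ab <- adapted_pair(envs[[1]], envs[[4]], mset)
  k_ba <- adapted_pair(envs[[4]], envs[[1]], mset)
  expect_lt(abs(k_ab - k_ba), 1e-12)
  # relabel structure 1's atoms by the swap mapping q
  e1 <- envs[[1]]
  q <- mset$perms[[2]]
  reordered <- e1
  for (cp in unique(e1$copy)) {
    rows <- which(e1$copy == cp)
    reordered$spectra[rows, ] <- e1$spectra[rows[q], ]
  }
  expect_lt(abs(adapted_pair(reordered, envs[[4]], mset) - k_ab), 1e-12)
})

test_that("kernel matrices match pairwise evaluation and flag duplicates", {
  envs <- tri_envs()[1:4]
  mset <- tri_mset()
  K <- build_kernel_matrix(envs, "adapted", mset = mset)
  for (i in 1:4) {
    for (j in 1:4) {
      expect_equal(K[i, j], adapted_pair(envs[[i]], envs[[j]], mset),
                   tolerance = 1e-10)
    }
  }
  expect_lt(max(abs(unclass(K) - t(unclass(K)))), 1e-12)
  # duplicated structure gives identical rows/columns
  K2 <- build_kernel_matrix(envs[c(1, 1, 2)], "adapted", mset = mset)
  expect_equal(unname(K2[1, ]), unname(K2[2, ]))
  # single-structure set
  K1 <- build_kernel_matrix(envs[1], "average")
  expect_equal(dim(unclass(K1)), c(1L, 1L))
})

test_that("normalization yields unit diagonal and correct off-diagonals", {
  K <- structure(matrix(c(4, 2, 2, 9), 2, 2), labels = c("a", "b"),
                 kernel_type = "average", normalized = FALSE,
                 params_hash = "h",
                 class = c("kernel_matrix", "matrix", "array"))
  Kn <- normalize_kernel(K)
  expect_equal(matrix(unclass(Kn), 2, 2), rbind(c(1, 1 / 3), c(1 / 3, 1)))
  cI <- structure(diag(5, 3), class = c("kernel_matrix", "matrix", "array"))
  expect_equal(matrix(unclass(normalize_kernel(cI)), 3, 3), diag(3))
  bad <- matrix(c(0, 0, 0, 1), 2, 2)
  expect_error(normalize_kernel(bad), "degenerate")
})

test_that("PSD checking reports eigenvalue bounds", {
  ok <- check_psd(diag(3))
  expect_true(ok$pass)
  expect_equal(ok$min_eigenvalue, 1)
  bad <- check_psd(matrix(c(1, 2, 2, 1), 2, 2))
  expect_false(bad$pass)
  expect_equal(bad$min_eigenvalue, -1)
})

test_that("adapted kernels are PSD on valid sets and refuse invalid ones", {
  # symmetric molecule, consistent Z'
  envs <- ab2_envs()
  mset <- find_mappings(make_molecule("symmetric_AB2"))
  K <- normalize_kernel(build_kernel_matrix(envs, "adapted", mset = mset))
  expect_true(check_psd(K)$pass)
  expect_lt(max(abs(diag(unclass(K)) - 1)), 1e-10)
  # asymmetric molecule, mixed Z'
  landm <- make_landscape(8, template = "asymmetric_triatomic",
                          zprime_choices = c(1, 2), seed = 55)
  envsm <- lapply(landm$structures, compute_environments,
                  params = tri_params())
  Km <- normalize_kernel(build_kernel_matrix(envsm, "adapted",
                                             mset = tri_mset()))
  expect_true(check_psd(Km)$pass)
  # symmetric molecule, mixed Z': refused
  lands <- make_landscape(6, template = "symmetric_AB2",
                          density_range = c(0.5, 0.7),
                          zprime_choices = c(1, 2), seed = 32)
  envss <- lapply(lands$structures, compute_environments,
                  params = ab2_params())
  zp <- vapply(lands$structures, function(s) s$zprime, integer(1))
  expect_gt(length(unique(zp)), 1)
  expect_error(build_kernel_matrix(envss, "adapted", mset = mset),
               "mixed Z'")
  expect_error(adapted_pair(envss[[which(zp == 1)[1]]],
                            envss[[which(zp == 2)[1]]], mset),
               "mixed Z'")
})

test_that("kernel save/load round-trips values and metadata", {
  K <- tri_kernel("adapted")
  prefix <- withr::local_tempfile()
  save_kernel(K, prefix)
  K2 <- load_kernel(prefix)
  expect_lt(max(abs(unclass(K2) - unclass(K))), 1e-12)
  expect_identical(attr(K2, "kernel_type"), "adapted")
  expect_true(attr(K2, "normalized"))
  expect_identical(attr(K2, "labels"), attr(K, "labels"))
})
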