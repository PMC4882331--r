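# Interconformer PCA: covariance, eigen-decomposition, projection.

test_that("covariance matches hand-computable cases and the loop oracle", {
  # identical conformers -> zero matrix
  same <- array(rep(helix_coords(4), each = 3), dim = c(3, 4, 3))
  expect_equal(max(abs(build_covariance(same))), 0, tolerance = 1e-12)
  # two single-atom conformers at (0,0,0) and (2,0,0): C_xx = 1, rest 0
  # (deviations are +-1 about the mean (1,0,0)); embedded in 4 static atoms
  # to satisfy the dimension requirements of downstream checks
  one <- array(0, dim = c(2, 1, 3))
  one[2, 1, 1] <- 2
  cov1 <- build_covariance(one)
  expect_equal(cov1[1, 1], 1)
  expect_equal(sum(abs(cov1)) - abs(cov1[1, 1]), 0)
  # random ensemble vs brute-force double loop over coordinate pairs
  coords <- rand_coords(5, 3, seed = 21)
  expect_lt(max(abs(build_covariance(coords) - brute_covariance(coords))), 1e-12)
  expect_error(build_covariance(coords[1, , , drop = FALSE]), "at least 2")
})

test_that("fit_pca returns sorted orthonormal components with exact fractions", {
  cov <- diag(c(4, 1, 0))
  m <- suppressWarnings(fit_pca(cov, k = 3))  # rank-2 input, k = 3: warns by design
  expect_equal(m$eigenvalues, c(4, 1, 0))
  expect_equal(m$variance_fractions, c(0.8, 0.2, 0))
  coords <- rand_coords(6, 4, seed = 3)
  cc <- build_covariance(coords)
  mm <- suppressWarnings(fit_pca(cc, k = 5))
  gram <- crossprod(mm$components)
  expect_lt(max(abs(gram - diag(5))), 1e-8)
  expect_true(all(diff(mm$eigenvalues) <= 1e-12))
  # spectrum sums to the trace
  full <- suppressWarnings(fit_pca(cc, k = 12))
  expect_equal(sum(full$eigenvalues), sum(diag(cc)), tolerance = 1e-6)
  # sign convention: largest-magnitude entry positive
  for (j in 1:5) expect_gt(mm$components[which.max(abs(mm$components[, j])), j], 0)
})

test_that("asking for more components than the rank warns", {
  same_dir <- array(0, dim = c(4, 2, 3))
  for (i in 1:4) same_dir[i, , ] <- helix_coords(2) + (i - 2.5) * 0.3
  cc <- build_covariance(same_dir)
  expect_warning(fit_pca(cc, k = 4), "rank")
})

test_that("projection is zero at the mean and complete over the full basis", {
  spec <- synthetic_spec(n_residues = 12, domain_partition = list(1:6, 7:12),
                         basin_centers = c(0, 25), basin_sd = 2, noise_sd = 0.2,
                         n_conformers = 10, seed = 13)
  ens <- gen_basin_ensemble(spec)
  model <- conformer_pca(ens, k = 5)
  sc_mean <- project(model, model$mean_coords)
  expect_lt(max(abs(as.matrix(sc_mean[, -1]))), 1e-8)
  # full-basis reconstruction returns the deviation vector
  sup <- iterative_mean_superpose(ens)
  cc <- build_covariance(coords_array(sup))
  full <- suppressWarnings(fit_pca(cc, k = 36, mean_coords = attr(sup, "mean_coords")))
  conf <- coords_array(sup)[3, , ]
  fit <- superpose(conf, full$mean_coords)
  dev <- as.vector(t(fit$coords[1, , ])) - as.vector(t(full$mean_coords))
  sc <- suppressWarnings(as.numeric(as.matrix(project(full, conf)[, -1])))
  recon <- as.vector(full$components %*% sc)
  expect_lt(max(abs(recon - dev)), 1e-8)
  # residue-count mismatch is an error
  expect_error(project(model, helix_coords(5)), "mismatch")
})

test_that("a planted 1-D hinge direction is recovered by PC1", {
  spec <- synthetic_spec(n_residues = 20, domain_partition = list(1:10, 11:20),
                         basin_centers = c(0, 20), basin_sd = 0, noise_sd = 0,
                         n_conformers = 8, seed = 31)
  ens <- gen_basin_ensemble(spec)
  model <- suppressWarnings(conformer_pca(ens, k = 2))  # noiseless: rank 1
  gt <- attr(ens, "ground_truth")
  s1 <- superpose(gt$basin_structures[[1]], model$mean_coords)$coords[1, , ]
  s2 <- superpose(gt$basin_structures[[2]], model$mean_coords)$coords[1, , ]
  planted <- as.vector(t(s2)) - as.vector(t(s1))
  planted <- planted / sqrt(sum(planted^2))
  expect_gte(abs(sum(planted * model$components[, 1])), 0.99)
})

test_that("variance fractions are invariant to a global rotation of the input", {
  spec <- synthetic_spec(n_residues = 15, domain_partition = list(1:7, 8:15),
                         basin_centers = c(0, 25), basin_sd = 3, noise_sd = 0.3,
                         n_conformers = 12, seed = 8)
  ens <- gen_basin_ensemble(spec)
  model <- conformer_pca(ens, k = 4)
  withr::with_seed(77, r <- random_rotation_matrix())
  rot <- ens
  for (i in seq_along(rot$xyz)) rot$xyz[[i]] <- rot$xyz[[i]] %*% r
  model_rot <- conformer_pca(rot, k = 4)
  expect_lt(max(abs(model$variance_fractions - model_rot$variance_fractions)), 1e-8)
})

test_that("PC1 variance fraction is stable under 50% subsampling", {
  spec <- synthetic_spec(n_residues = 20, domain_partition = list(1:10, 11:20),
                         basin_centers = c(0, 25), basin_sd = 2, noise_sd = 0.3,
                         n_conformers = 40, seed = 19)
  ens <- gen_basin_ensemble(spec)
  full <- conformer_pca(ens, k = 2)
  withr::with_seed(55, keep <- sort(sample(40, 20)))
  sub <- conformer_ensemble(ens$xyz[keep], ens$labels[keep], ens$ids[keep])
  half <- conformer_pca(sub, k = 2)
  expect_lt(abs(full$variance_fractions[1] - half$variance_fractions[1]), 0.05)
})

test_that("tidy and glance summarise a pca model", {
  spec <- synthetic_spec(n_residues = 10, domain_partition = list(1:5, 6:10),
                         n_conformers = 6, seed = 4)
  model <- conformer_pca(gen_basin_ensemble(spec), k = 3)
  td <- tidy(model)
  expect_equal(nrow(td), 3)
  expect_equal(td$cumulative_fraction, cumsum(td$variance_fraction))
  gl <- glance(model)
  expect_equal(gl$pc1_fraction, model$variance_fractions[1])
})
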