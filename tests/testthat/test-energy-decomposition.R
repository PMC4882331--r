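# Pair-energy matrices and the Energy Decomposition Method.

test_that("pair energies reproduce Coulomb's law and the LJ minimum", {
  # two +1e charges 1 A apart, no LJ
  coords <- array(0, dim = c(1, 2, 3))
  coords[1, 2, 1] <- 1
  params <- data.frame(residue = 1:2, charge = 1, sigma = 0, epsilon = 0)
  m <- pair_energy_matrix(coords, params)
  expect_equal(m[1, 2], 332.0636, tolerance = 1e-10)
  # two neutral atoms at the LJ minimum r = 2^(1/6) sigma -> -epsilon
  sig <- 3.4; eps <- 0.25
  coords2 <- array(0, dim = c(1, 2, 3))
  coords2[1, 2, 1] <- 2^(1 / 6) * sig
  params2 <- data.frame(residue = 1:2, charge = 0, sigma = sig, epsilon = eps)
  m2 <- pair_energy_matrix(coords2, params2)
  expect_equal(m2[1, 2], -eps, tolerance = 1e-12)
})

test_that("multi-atom multi-frame energies match the loop oracle", {
  withr::with_seed(24, {
    coords <- array(rnorm(2 * 7 * 3, sd = 3) + 8, dim = c(2, 7, 3))
    params <- data.frame(residue = c(1, 1, 2, 2, 2, 3, 3),
                         charge = round(runif(7, -0.5, 0.5), 3),
                         sigma = round(runif(7, 2.5, 3.8), 3),
                         epsilon = round(runif(7, 0.05, 0.3), 3))
  })
  m <- pair_energy_matrix(coords, params)
  expect_lt(max(abs(unclass(m) - brute_pair_energy(coords, params))), 1e-10)
  expect_true(isSymmetric(unclass(m)))
  expect_equal(diag(m), rep(0, 3), ignore_attr = TRUE)
  # missing parameters and coincident atoms are errors
  bad <- params; bad$charge[3] <- NA
  expect_error(pair_energy_matrix(coords, bad), "without parameters")
  clash <- coords; clash[1, 3, ] <- clash[1, 6, ]
  expect_error(pair_energy_matrix(clash, params), "zero interatomic distance")
})

test_that("the decomposition recovers a planted rank-1 matrix and its spectrum sums to the trace", {
  n <- 30
  withr::with_seed(2, w <- rnorm(n))
  w <- w / sqrt(sum(w^2))
  m <- -100 * tcrossprod(w)
  dec <- edm_decompose(m)
  expect_equal(dec$values[1], -100, tolerance = 1e-8)
  expect_gte(abs(sum(dec$vectors[, 1] * w)), 1 - 1e-10)
  expect_equal(sum(dec$values), sum(diag(m)), tolerance = 1e-8)
  # full-spectrum reconstruction reproduces the matrix
  recon <- dec$vectors %*% (dec$values * t(dec$vectors))
  expect_lt(max(abs(recon - m)), 1e-8)
  # asymmetry is rejected
  bad <- m; bad[1, 2] <- bad[1, 2] + 1
  expect_error(edm_decompose(bad), "symmetric")
})

test_that("noisy rank-1 matrices still point at the planted eigenvector", {
  n <- 30
  withr::with_seed(2, w <- rnorm(n))
  w <- w / sqrt(sum(w^2))
  clean <- -100 * tcrossprod(w)
  dots <- vapply(1:20, function(s) {
    withr::with_seed(1000 + s, {
      e <- matrix(rnorm(n * n), n, n)
    })
    noisy <- clean + (e + t(e)) / 2
    abs(sum(edm_decompose(noisy)$vectors[, 1] * w))
  }, numeric(1))
  expect_true(all(dots >= 0.95))
})

test_that("essential selection finds one eigenvector per planted block", {
  spec <- synthetic_spec(n_residues = 75, domain_partition = list(1:20, 21:50, 51:75),
                         energy_block_strength = 4, energy_noise_sd = 0, seed = 1)
  m <- gen_energy_matrix(spec)
  dec <- edm_decompose(m)
  ess <- select_essential(dec)
  expect_length(ess, 3)
  # each selected vector's significant components sit in exactly one block
  gt <- attr(m, "ground_truth")$domain_labels
  thresh <- 1 / sqrt(75)
  for (k in ess) {
    sig <- which(abs(dec$vectors[, k]) > thresh)
    expect_equal(length(unique(gt[sig])), 1)
  }
  # a rank-1 single-domain matrix needs only the lowest eigenvector
  withr::with_seed(5, w1 <- abs(rnorm(40)) + 0.2)
  w1 <- w1 / sqrt(sum(w1^2))
  ess1 <- select_essential(edm_decompose(-50 * tcrossprod(w1)))
  expect_equal(as.integer(ess1), 1L)
})

test_that("pure-noise matrices terminate, often by the min_gain early stop", {
  # null simulation: noise eigenvectors are delocalised, so unlike planted
  # blocks they carry no one-domain structure; the greedy either stops early
  # by min_gain (warning, coverage below target) or stacks several
  # delocalised vectors
  runs <- lapply(1:20, function(s) {
    spec <- synthetic_spec(n_residues = 30, domain_partition = list(1:30),
                           energy_block_strength = 0, energy_noise_sd = 1,
                           seed = 2000 + s)
    dec <- edm_decompose(gen_energy_matrix(spec))
    warned <- FALSE
    ess <- withCallingHandlers(select_essential(dec),
      warning = function(w) { warned <<- TRUE; invokeRestart("muffleWarning") })
    list(coverage = attr(ess, "coverage"), k = length(ess), warned = warned)
  })
  expect_true(all(vapply(runs, function(r) r$k >= 1, logical(1))))
  warned <- vapply(runs, function(r) r$warned, logical(1))
  expect_gt(sum(warned), 5)
  for (r in runs[warned]) expect_lt(r$coverage, 0.9)
})

test_that("the folding matrix reconstructs within blocks and vanishes off-block", {
  spec <- synthetic_spec(n_residues = 75, domain_partition = list(1:20, 21:50, 51:75),
                         energy_block_strength = 4, energy_noise_sd = 0.4, seed = 9)
  m <- gen_energy_matrix(spec)
  dec <- edm_decompose(m)
  ess <- select_essential(dec)
  fold <- folding_matrix(dec, ess)
  gt <- attr(m, "ground_truth")$domain_labels
  same <- outer(gt, gt, `==`); diag(same) <- FALSE
  off <- !same; diag(off) <- FALSE
  expect_lt(mean(abs(fold[off])), 0.1 * mean(abs(fold[same])))
  # the full spectrum reproduces M
  full <- folding_matrix(dec, seq_len(75))
  expect_lt(max(abs(full - unclass_m(m))), 1e-8)
  # rank-1 essential set is exact
  withr::with_seed(3, w <- rnorm(20))
  w <- w / sqrt(sum(w^2))
  d1 <- edm_decompose(-10 * tcrossprod(w))
  expect_equal(folding_matrix(d1, 1L), -10 * tcrossprod(w),
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("symbolization thresholds at the mean negative entry", {
  z <- matrix(0, 6, 6)
  expect_equal(sum(symbolize(z)), 0)
  one <- z; one[2, 5] <- one[5, 2] <- -10
  s <- symbolize(one)
  expect_equal(sum(s), 2)
  expect_equal(s[2, 5], 1)
  expect_error(symbolize(one, rule = "magic"), "unknown symbolization rule")
  # quantile rule keeps the q most negative fraction
  withr::with_seed(8, r <- matrix(rnorm(400), 20, 20))
  r <- (r + t(r)) / 2
  sq <- symbolize(r, rule = "quantile:0.1")
  expect_lt(abs(mean(sq) - 0.1), 0.02)
  # planted blocks: 1-entries lie within blocks with precision >= 0.9
  spec <- synthetic_spec(n_residues = 75, domain_partition = list(1:20, 21:50, 51:75),
                         energy_block_strength = 4, energy_noise_sd = 0.5, seed = 14)
  m <- gen_energy_matrix(spec)
  dec <- edm_decompose(m)
  fold <- folding_matrix(dec, select_essential(dec))
  sym <- symbolize(fold)
  gt <- attr(m, "ground_truth")$domain_labels
  same <- outer(gt, gt, `==`)
  expect_gte(sum(sym == 1 & same) / sum(sym == 1), 0.9)
})

test_that("domains are the connected components above the size threshold", {
  gt <- rep(c("1", "2", "3"), c(20, 30, 25))
  sym <- (outer(gt, gt, `==`)) * 1
  diag(sym) <- 0
  dom <- cluster_domains(sym)
  expect_equal(mclust::adjustedRandIndex(dom, gt), 1)
  expect_equal(unname(dom), gt)
  # empty matrix: all unassigned
  expect_true(all(cluster_domains(matrix(0, 10, 10)) == "unassigned"))
  # one spurious bridge merges two components (documented behaviour)
  bridged <- sym
  bridged[1, 21] <- bridged[21, 1] <- 1
  dom2 <- cluster_domains(bridged)
  expect_equal(length(setdiff(unique(dom2), "unassigned")), 2)
  # components below min_size stay unassigned
  tiny <- matrix(0, 8, 8)
  tiny[1, 2] <- tiny[2, 1] <- 1
  expect_true(all(cluster_domains(tiny, min_size = 5) == "unassigned"))
})

test_that("stabilization profile is the column sums and hotspots sit below its mean", {
  toy <- matrix(c(0, -2, -1, -2, 0, 0, -1, 0, 0), 3, 3)
  expect_equal(unname(stabilization_profile(toy)), c(-3, -2, -1))
  expect_equal(unname(stabilization_profile(matrix(0, 4, 4))), rep(0, 4))
  withr::with_seed(4, r <- matrix(rnorm(100), 10, 10))
  r <- (r + t(r)) / 2
  brute <- vapply(1:10, function(i) sum(r[, i]), numeric(1))
  expect_equal(unname(stabilization_profile(r)), brute)
  # constant profile -> no hotspots; one deep column -> that residue only
  expect_length(select_hotspots(rep(-3, 6)), 0)
  expect_equal(unname(select_hotspots(c(-10, 0, 0, 0))), 1L)
})

test_that("the EDM is equivariant under residue permutation", {
  spec <- synthetic_spec(n_residues = 40, domain_partition = list(1:15, 16:40),
                         energy_block_strength = 3, energy_noise_sd = 0.3,
                         hotspot_columns = c(5, 22), hotspot_strength = 8, seed = 21)
  m <- unclass_m(gen_energy_matrix(spec))
  withr::with_seed(50, perm <- sample(40))
  mp <- m[perm, perm]
  r1 <- suppressWarnings(edm(m))
  r2 <- suppressWarnings(edm(mp))
  expect_equal(unname(r2$stabilization), unname(r1$stabilization[perm]), tolerance = 1e-8)
  expect_setequal(perm[unname(r2$hotspots)], unname(r1$hotspots))
  # domain partitions agree up to relabelling
  expect_equal(mclust::adjustedRandIndex(r2$domains, r1$domains[perm]), 1)
})

test_that("total energy is conserved by the full-spectrum folding matrix", {
  spec <- synthetic_spec(n_residues = 30, domain_partition = list(1:30),
                         energy_block_strength = 2, energy_noise_sd = 0.5, seed = 71)
  m <- unclass_m(gen_energy_matrix(spec))
  dec <- edm_decompose(m)
  full <- folding_matrix(dec, seq_len(30))
  expect_equal(sum(full), sum(m), tolerance = 1e-8 * max(1, abs(sum(m))))
})

test_that("the rank-1 approximation error vanishes as noise does", {
  errs <- vapply(c(2, 1, 0.25), function(ns) {
    spec <- synthetic_spec(n_residues = 30, domain_partition = list(1:30),
                           energy_block_strength = 5, energy_noise_sd = ns, seed = 13)
    m <- unclass_m(gen_energy_matrix(spec))
    dec <- edm_decompose(m)
    approx1 <- dec$values[1] * tcrossprod(dec$vectors[, 1])
    norm(m - approx1, "F") / norm(m, "F")
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})
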