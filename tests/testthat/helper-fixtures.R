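# Fixture builders and independent brute-force oracles. The oracles are
# deliberately written as plain loops, independent of the package's
# vectorised implementations.

rand_coords <- function(n_frames, n_res, sd = 2, seed = 1) {
  withr::with_seed(seed,
    array(rnorm(n_frames * n_res * 3, sd = sd) + 5,
          dim = c(n_frames, n_res, 3)))
}

random_rotation_matrix <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rigid_transform_frames <- function(coords) {
  out <- coords
  for (f in seq_len(dim(coords)[1])) {
    r <- random_rotation_matrix()
    t <- rnorm(3, sd = 20)
    out[f, , ] <- sweep(coords[f, , ] %*% r, 2, t, `+`)
  }
  out
}

# Eq-style population variance of pairwise distances, by triple loop.
brute_fluctuation <- function(coords) {
  nf <- dim(coords)[1]; n <- dim(coords)[2]
  a <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- numeric(nf)
    for (f in seq_len(nf)) d[f] <- sqrt(sum((coords[f, i, ] - coords[f, j, ])^2))
    a[i, j] <- mean((d - mean(d))^2)
  }
  a
}

# Population covariance of flattened coordinates, by double loop.
brute_covariance <- function(coords) {
  m <- dim(coords)[1]
  x <- t(vapply(seq_len(m), function(i) as.vector(t(coords[i, , ])),
                numeric(dim(coords)[2] * 3)))
  mu <- colMeans(x)
  p <- ncol(x)
  cc <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p))
    cc[i, j] <- mean((x[, i] - mu[i]) * (x[, j] - mu[j]))
  cc
}

# Per-frame atom-pair Coulomb + LJ sums aggregated to residues, by loops.
brute_pair_energy <- function(coords, params) {
  ke <- 332.0636
  nf <- dim(coords)[1]; na <- dim(coords)[2]
  n_res <- max(params$residue)
  m <- matrix(0, n_res, n_res)
  for (f in seq_len(nf)) {
    mf <- matrix(0, n_res, n_res)
    for (a in seq_len(na)) for (b in seq_len(na)) {
      if (a == b) next
      ri <- params$residue[a]; rj <- params$residue[b]
      if (ri == rj) next
      r <- sqrt(sum((coords[f, a, ] - coords[f, b, ])^2))
      sig <- (params$sigma[a] + params$sigma[b]) / 2
      eps <- sqrt(params$epsilon[a] * params$epsilon[b])
      e <- ke * params$charge[a] * params$charge[b] / r +
        4 * eps * ((sig / r)^12 - (sig / r)^6)
      mf[ri, rj] <- mf[ri, rj] + e / 2  # each unordered atom pair visited twice
      mf[rj, ri] <- mf[rj, ri] + e / 2
    }
    m <- m + mf
  }
  m / nf
}

# Minimal PDB writer for read_conformers fixtures. `residues` is a data
# frame with chain, resno, resid and optional alt/occ/insert columns;
# coords is an N x 3 matrix (or list of them, one per MODEL).
write_tiny_pdb <- function(path, residues, coords) {
  if (is.matrix(coords)) coords <- list(coords)
  lines <- character(0)
  for (m in seq_along(coords)) {
    if (length(coords) > 1) lines <- c(lines, sprintf("MODEL     %4d", m))
    for (i in seq_len(nrow(residues))) {
      alt <- if ("alt" %in% names(residues)) residues$alt[i] else " "
      occ <- if ("occ" %in% names(residues)) residues$occ[i] else 1
      ins <- if ("insert" %in% names(residues)) residues$insert[i] else " "
      name <- if ("elety" %in% names(residues)) residues$elety[i] else "CA"
      lines <- c(lines, sprintf(
        "ATOM  %5d %s%s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
        i, formatC(name, width = -4), alt, residues$resid[i],
        residues$chain[i], residues$resno[i], ins,
        coords[[m]][i, 1], coords[[m]][i, 2], coords[[m]][i, 3], occ, 0))
    }
    if (length(coords) > 1) lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

# A compact helical-ish chain usable as a well-conditioned structure.
helix_coords <- function(n) {
  t <- seq_len(n)
  cbind(2.3 * cos(t), 2.3 * sin(t), 1.5 * t)
}

# strip polconf matrix classes/attrs for plain-matrix comparisons
unclass_m <- function(m) {
  d <- dim(m)
  m <- as.numeric(m)
  dim(m) <- d
  m
}

digest_file <- function(f) unname(tools::md5sum(f))
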