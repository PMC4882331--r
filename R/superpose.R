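# Kabsch least-squares superposition and alignment of shared residues.

#' Superpose conformations onto a reference structure
#'
#' Rigid-body least-squares fit (Kabsch): each conformer is rotated and
#' translated to minimise the Calpha RMSD to `reference`. Only proper
#' rotations (determinant +1) are allowed, so a mirror image cannot be fitted
#' onto its original — the standard structural-biology convention.
#'
#' @param coords numeric array `m x N x 3`, or a single `N x 3` matrix.
#' @param reference numeric `N x 3` matrix with finite entries, `N >= 4`.
#' @return a list with `coords` (superposed, `m x N x 3`) and `rmsd`
#'   (numeric vector of minimised RMSD values, Angstrom).
#' @export
superpose <- function(coords, reference) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(1, dim(coords)))
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  n <- dim(coords)[2]
  if (n < 4) abort("at least 4 positions are required for superposition")
  if (!all(is.finite(reference)) || !identical(dim(reference), as.integer(c(n, 3))))
    abort("reference must be a finite N x 3 matrix matching coords")
  ref_c <- scale(reference, scale = FALSE)
  if (is_collinear(ref_c)) abort("degenerate (collinear) reference coordinates")
  out <- coords
  rmsd <- numeric(dim(coords)[1])
  for (i in seq_len(dim(coords)[1])) {
    fit <- kabsch(coords[i, , ], reference)
    out[i, , ] <- fit$coords
    rmsd[i] <- fit$rmsd
  }
  list(coords = out, rmsd = rmsd)
}

# Optimal proper rotation of x onto y (both N x 3); returns transformed
# coords and the minimised RMSD.
kabsch <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  x0 <- sweep(x, 2, cx); y0 <- sweep(y, 2, cy)
  if (is_collinear(x0)) abort("degenerate (collinear) coordinates")
  h <- crossprod(x0, y0)
  s <- svd(h)
  d <- sign(det(s$u) * det(s$v))
  r <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- sweep(x0 %*% r, 2, cy, `+`)
  list(coords = fitted, rotation = r,
       rmsd = sqrt(mean(rowSums((fitted - y)^2))))
}

is_collinear <- function(centered, tol = 1e-8) {
  sv <- svd(centered, nu = 0, nv = 0)$d
  length(sv) < 2 || sv[2] <= tol * max(sv[1], 1)
}

#' Iteratively superpose an ensemble onto its mean structure
#'
#' Conformers are fitted to the current ensemble mean, the mean is
#' recomputed, and the two steps are repeated until the mean moves less than
#' `tol` (RMSD between successive means) or `max_iter` is reached. The final
#' mean is brought to a canonical pose (centroid at the origin, principal
#' axes of the mean along the coordinate axes) so the result does not depend
#' on the global pose of the input.
#'
#' @param ensemble an aligned [conformer_ensemble()].
#' @param tol convergence tolerance in Angstrom (default `1e-6`).
#' @param max_iter maximum number of iterations (default 50); on
#'   non-convergence a warning is emitted and the best iterate returned.
#' @return the ensemble with superposed coordinates; the converged mean is
#'   attached as attribute `"mean_coords"` and the per-conformer RMSD to the
#'   mean as `"rmsd"`.
#' @export
iterative_mean_superpose <- function(ensemble, tol = 1e-6, max_iter = 50) {
  arr <- coords_array(ensemble)
  m <- dim(arr)[1]
  if (m == 1) {
    res <- ensemble
    attr(res, "mean_coords") <- arr[1, , ]
    attr(res, "rmsd") <- 0
    return(res)
  }
  mean_coords <- arr[1, , ]
  rmsd <- numeric(m)
  for (iter in seq_len(max_iter)) {
    fit <- superpose(arr, mean_coords)
    arr <- fit$coords
    rmsd <- fit$rmsd
    new_mean <- apply(arr, c(2, 3), mean)
    shift <- sqrt(mean(rowSums((new_mean - mean_coords)^2)))
    mean_coords <- new_mean
    if (shift < tol) break
    if (iter == max_iter)
      warn(sprintf("iterative superposition did not converge in %d iterations (last shift %.3g)",
                   max_iter, shift))
  }
  canon <- canonical_rotation(mean_coords)
  centroid <- colMeans(mean_coords)
  mean_coords <- sweep(mean_coords, 2, centroid) %*% canon
  for (i in seq_len(m)) arr[i, , ] <- sweep(arr[i, , ], 2, centroid) %*% canon
  out <- ensemble
  for (i in seq_len(m)) out$xyz[[i]] <- arr[i, , ]
  attr(out, "mean_coords") <- mean_coords
  attr(out, "rmsd") <- rmsd
  out
}

# Proper rotation aligning the principal axes of a centred structure with the
# coordinate axes, with a sign convention making the result reproducible.
canonical_rotation <- function(coords) {
  centered <- sweep(coords, 2, colMeans(coords))
  ev <- eigen(crossprod(centered), symmetric = TRUE)
  v <- ev$vectors
  for (j in 1:3) if (v[which.max(abs(v[, j])), j] < 0) v[, j] <- -v[, j]
  if (det(v) < 0) v[, 3] <- -v[, 3]
  v
}

#' Restrict an ensemble to alignment-shared residues
#'
#' One-letter sequences are taken from the residue labels and each conformer
#' is globally aligned to a reference conformer (the longest sequence;
#' ties broken lexicographically so the result does not depend on input
#' order) with identity scoring: match +1, mismatch 0, gap -1. A reference
#' column is shared when every conformer places a residue there. If any
#' pairwise alignment has no identical column at all the sequences have no
#' alignable core and an error is raised.
#'
#' @param ensemble a [conformer_ensemble()] with at least 2 conformers.
#' @return the ensemble masked to shared positions; `shared_mask` records,
#'   over the reference conformer's positions, which columns were kept.
#' @export
align_shared <- function(ensemble) {
  if (n_conformers(ensemble) < 2) abort("align_shared needs at least 2 conformers")
  seqs <- vapply(ensemble$labels, function(l) paste(l$aa, collapse = ""), character(1))
  ref <- order(-nchar(seqs), seqs)[1]
  ref_n <- nchar(seqs[ref])
  occupied <- matrix(FALSE, nrow = n_conformers(ensemble), ncol = ref_n)
  maps <- vector("list", n_conformers(ensemble))  # ref position -> conformer position
  occupied[ref, ] <- TRUE
  maps[[ref]] <- seq_len(ref_n)
  for (i in seq_len(n_conformers(ensemble))) {
    if (i == ref) next
    al <- align_pair(seqs[ref], seqs[i])
    if (al$n_identical == 0) abort("no shared residues")
    occupied[i, al$ref_pos] <- TRUE
    map <- rep(NA_integer_, ref_n)
    map[al$ref_pos] <- al$other_pos
    maps[[i]] <- map
  }
  shared <- apply(occupied, 2, all)
  if (!any(shared)) abort("no shared residues")
  xyz <- vector("list", n_conformers(ensemble))
  labels <- vector("list", n_conformers(ensemble))
  for (i in seq_len(n_conformers(ensemble))) {
    idx <- maps[[i]][shared]
    xyz[[i]] <- ensemble$xyz[[i]][idx, , drop = FALSE]
    labels[[i]] <- ensemble$labels[[i]][idx, , drop = FALSE]
  }
  out <- conformer_ensemble(xyz, labels, ensemble$ids)
  out$residue_labels <- labels[[ref]]
  out$uniform <- TRUE
  out$shared_mask <- shared
  out
}

# Global (Needleman-Wunsch) alignment via Biostrings with identity scoring.
# Returns aligned position pairs and the number of identical columns.
align_pair <- function(a, b) {
  letters_all <- c(LETTERS)
  subst <- matrix(0, 26, 26, dimnames = list(letters_all, letters_all))
  diag(subst) <- 1
  al <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                      substitutionMatrix = subst,
                                      gapOpening = 0, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  ref_pos <- integer(0); other_pos <- integer(0); n_ident <- 0L
  ia <- 0L; ib <- 0L
  for (k in seq_along(pa)) {
    if (pa[k] != "-") ia <- ia + 1L
    if (sa[k] != "-") ib <- ib + 1L
    if (pa[k] != "-" && sa[k] != "-") {
      ref_pos <- c(ref_pos, ia)
      other_pos <- c(other_pos, ib)
      if (pa[k] == sa[k]) n_ident <- n_ident + 1L
    }
  }
  list(ref_pos = ref_pos, other_pos = other_pos, n_identical = n_ident)
}
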