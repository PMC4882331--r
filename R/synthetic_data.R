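# Synthetic generators with planted ground truth.
#
# The generators stand in for the study's inputs: crystal-ensemble basins
# (open/ajar/closed-like), hinge trajectories with rigid subdomains, and
# block-structured attractive interaction matrices with planted hotspot
# columns. Geometry is a coarse Calpha chain (3.8 A spacing, 4 A excluded
# volume) — sufficient for the distance, PCA and energy statistics, with no
# claim to force-field realism. Each generator draws from a single stream
# seeded by `spec$seed`, never touching the global RNG state.

#' Specification of a synthetic system
#'
#' @param n_residues chain length (default 100).
#' @param domain_partition list of contiguous 1-based index ranges covering
#'   `1..n_residues` without overlap; default: two equal halves.
#' @param hinge_amplitude hinge rotation amplitude in degrees.
#' @param noise_sd isotropic Gaussian coordinate noise, Angstrom.
#' @param basin_centers hinge angles (degrees) of the conformational basins.
#' @param basin_sd within-basin angular spread, degrees.
#' @param energy_block_strength magnitude of the attractive within-domain
#'   interaction, kcal/mol (entries are drawn around minus this value).
#' @param hotspot_columns residue indices of planted hotspot columns.
#' @param hotspot_strength extra attraction on hotspot rows/columns,
#'   kcal/mol (magnitude).
#' @param energy_noise_sd sd of the symmetric Gaussian noise added to the
#'   energy matrix, kcal/mol.
#' @param n_frames,n_conformers trajectory / ensemble sizes.
#' @param seed integer RNG seed; identical spec + seed gives identical
#'   output.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_residues = 100,
                           domain_partition = NULL,
                           hinge_amplitude = 30,
                           noise_sd = 0.3,
                           basin_centers = c(0, 30),
                           basin_sd = 1,
                           energy_block_strength = 4,
                           hotspot_columns = integer(0),
                           hotspot_strength = 10,
                           energy_noise_sd = 0.5,
                           n_frames = 50,
                           n_conformers = 40,
                           seed = 1L) {
  domain_partition <- domain_partition %||% list(
    seq_len(floor(n_residues / 2)),
    (floor(n_residues / 2) + 1):n_residues)
  idx <- sort(unlist(domain_partition))
  if (!identical(idx, seq_len(n_residues)))
    abort("domain_partition must cover 1..n_residues without overlap")
  if (noise_sd < 0 || energy_noise_sd < 0) abort("noise sd must be >= 0")
  structure(list(
    n_residues = n_residues, domain_partition = domain_partition,
    hinge_amplitude = hinge_amplitude, noise_sd = noise_sd,
    basin_centers = basin_centers, basin_sd = basin_sd,
    energy_block_strength = energy_block_strength,
    hotspot_columns = as.integer(hotspot_columns),
    hotspot_strength = hotspot_strength, energy_noise_sd = energy_noise_sd,
    n_frames = n_frames, n_conformers = n_conformers, seed = as.integer(seed)
  ), class = "synthetic_spec")
}

domain_labels_of <- function(spec) {
  lab <- character(spec$n_residues)
  for (d in seq_along(spec$domain_partition))
    lab[spec$domain_partition[[d]]] <- as.character(d)
  lab
}

# Self-avoiding coarse chain: 3.8 A consecutive-Calpha steps with a
# persistence bias, non-adjacent beads kept >= 4 A apart.
gen_chain <- function(n, step = 3.8, excluded = 4) {
  coords <- matrix(0, n, 3)
  dir <- c(1, 0, 0)
  for (i in 2:n) {
    placed <- FALSE
    for (attempt in 1:200) {
      u <- rnorm(3)
      cand_dir <- 0.8 * dir + 0.6 * u / sqrt(sum(u^2))
      cand_dir <- cand_dir / sqrt(sum(cand_dir^2))
      cand <- coords[i - 1, ] + step * cand_dir
      if (i <= 3 || min(sqrt(colSums((t(coords[1:(i - 2), , drop = FALSE]) - cand)^2))) >= excluded) {
        coords[i, ] <- cand
        dir <- cand_dir
        placed <- TRUE
        break
      }
    }
    if (!placed) abort("self-avoiding chain generation failed")
  }
  coords
}

# Rodrigues rotation matrix: angle in degrees about unit axis.
rotation_about_axis <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  k <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
}

# Rotate the moving unit (all residues after domain 1) about a hinge axis
# through the boundary Calpha.
apply_hinge <- function(base, spec, axis, angle_deg) {
  moving <- setdiff(seq_len(spec$n_residues), spec$domain_partition[[1]])
  pivot <- base[max(spec$domain_partition[[1]]), ]
  r <- rotation_about_axis(axis, angle_deg)
  out <- base
  out[moving, ] <- sweep(sweep(base[moving, , drop = FALSE], 2, pivot) %*% t(r), 2, pivot, `+`)
  out
}

min_nonadjacent_dist <- function(coords) {
  d <- as.matrix(dist(coords))
  n <- nrow(d)
  d[cbind(seq_len(n), seq_len(n))] <- Inf
  d[cbind(seq_len(n - 1), 2:n)] <- Inf
  d[cbind(2:n, seq_len(n - 1))] <- Inf
  min(d)
}

# Draw a hinge axis whose extreme-angle pose stays self-avoiding and whose
# rotation sense moves the two domain centroids as requested.
pick_hinge_axis <- function(base, spec, amplitude, sense = c("closing", "opening")) {
  sense <- match.arg(sense)
  fixed <- spec$domain_partition[[1]]
  moving <- setdiff(seq_len(spec$n_residues), fixed)
  centroid_dist <- function(x)
    sqrt(sum((colMeans(x[fixed, , drop = FALSE]) - colMeans(x[moving, , drop = FALSE]))^2))
  d0 <- centroid_dist(base)
  for (attempt in 1:10) {
    u <- rnorm(3); axis <- u / sqrt(sum(u^2))
    for (s in c(1, -1)) {
      extreme <- apply_hinge(base, spec, axis, s * amplitude)
      d1 <- centroid_dist(extreme)
      goes_right_way <- if (sense == "closing") d1 < d0 - 1e-6 else d1 > d0 + 1e-6
      if (goes_right_way && min_nonadjacent_dist(extreme) > 1.0)
        return(s * axis)
    }
  }
  abort("could not find a self-avoiding hinge axis for this amplitude; reduce hinge_amplitude")
}

#' Generate a hinge-motion trajectory
#'
#' Domain 1 stays fixed; all later residues rotate rigidly about a hinge
#' axis through the inter-domain boundary Calpha. `mode = "closing"`
#' rotates linearly from 0 to the amplitude with the sense that shrinks the
#' inter-domain centroid distance; `"opening"` grows it; `"two_state"`
#' alternates between the two endpoint angles halfway through. Isotropic
#' Gaussian noise of sd `noise_sd` is added per frame.
#'
#' @param spec a [synthetic_spec()] with at least 2 domains and
#'   `n_frames >= 2`.
#' @param mode `"closing"`, `"opening"` or `"two_state"`.
#' @return a [trajectory()] with attribute `"ground_truth"`: list with
#'   `domain_labels`, `mode`, `amplitude`, `angles` and the suggested probe
#'   pair (one residue per domain, nearest each domain centroid).
#' @export
gen_hinge_trajectory <- function(spec, mode = c("closing", "opening", "two_state")) {
  mode <- match.arg(mode)
  if (length(spec$domain_partition) < 2) abort("a hinge needs at least 2 domains")
  if (spec$n_frames < 2) abort("n_frames must be >= 2")
  withr::with_seed(spec$seed, {
    base <- gen_chain(spec$n_residues)
    angles <- switch(mode,
      closing = seq(spec$hinge_amplitude, 0, length.out = spec$n_frames),
      opening = seq(0, spec$hinge_amplitude, length.out = spec$n_frames),
      two_state = rep(c(0, spec$hinge_amplitude), each = ceiling(spec$n_frames / 2))[seq_len(spec$n_frames)]
    )
    if (spec$hinge_amplitude == 0) {
      axis <- c(0, 0, 1)
    } else {
      # the extreme pose (angle = amplitude) is always the more open one:
      # "closing" then relaxes from it to the base pose, "opening" moves
      # toward it
      axis <- pick_hinge_axis(base, spec, spec$hinge_amplitude, "opening")
    }
    coords <- array(NA_real_, dim = c(spec$n_frames, spec$n_residues, 3))
    for (f in seq_len(spec$n_frames)) {
      frame <- apply_hinge(base, spec, axis, angles[f])
      if (spec$noise_sd > 0)
        frame <- frame + matrix(rnorm(length(frame), sd = spec$noise_sd), ncol = 3)
      coords[f, , ] <- frame
    }
    traj <- trajectory(coords)
    dom <- domain_labels_of(spec)
    probe <- vapply(list(spec$domain_partition[[1]],
                         setdiff(seq_len(spec$n_residues), spec$domain_partition[[1]])),
                    function(ix) {
      ctr <- colMeans(base[ix, , drop = FALSE])
      ix[which.min(colSums((t(base[ix, , drop = FALSE]) - ctr)^2))]
    }, integer(1))
    attr(traj, "ground_truth") <- list(domain_labels = dom, mode = mode,
                                       amplitude = spec$hinge_amplitude,
                                       angles = angles, probe_pair = probe)
    traj
  })
}

#' Generate a multi-basin conformer ensemble
#'
#' Conformers are assigned round-robin to the basins of
#' `spec$basin_centers`; each draws a hinge angle `N(center, basin_sd)` and
#' applies it to the common base chain, plus coordinate noise. The planted
#' basin memberships and the noiseless basin-center structures are recorded
#' as ground truth.
#'
#' @param spec a [synthetic_spec()] with `>= 2` basin centers and
#'   `n_conformers >= length(basin_centers)`.
#' @return a [conformer_ensemble()] with attribute `"ground_truth"`: list
#'   with `basin` (per-conformer index), `angles`, and `basin_structures`
#'   (noiseless `N x 3` matrices, one per basin center).
#' @export
gen_basin_ensemble <- function(spec) {
  nb <- length(spec$basin_centers)
  if (nb < 1) abort("at least one basin center is required")
  if (spec$n_conformers < nb) abort("n_conformers must be >= the number of basins")
  withr::with_seed(spec$seed, {
    base <- gen_chain(spec$n_residues)
    axis <- if (max(abs(spec$basin_centers)) > 0 || spec$basin_sd > 0)
      pick_hinge_axis(base, spec, max(abs(spec$basin_centers), 10), "opening")
    else c(0, 0, 1)
    basin <- rep(seq_len(nb), length.out = spec$n_conformers)
    angles <- spec$basin_centers[basin] +
      if (spec$basin_sd > 0) rnorm(spec$n_conformers, sd = spec$basin_sd) else 0
    xyz <- vector("list", spec$n_conformers)
    for (i in seq_len(spec$n_conformers)) {
      crd <- apply_hinge(base, spec, axis, angles[i])
      if (spec$noise_sd > 0)
        crd <- crd + matrix(rnorm(length(crd), sd = spec$noise_sd), ncol = 3)
      xyz[[i]] <- crd
    }
    labels <- make_residue_labels("A", seq_len(spec$n_residues), resid = "GLY")
    ens <- conformer_ensemble(xyz, rep(list(labels), spec$n_conformers))
    attr(ens, "ground_truth") <- list(
      basin = basin, angles = angles,
      basin_structures = lapply(spec$basin_centers,
                                function(a) apply_hinge(base, spec, axis, a)))
    ens
  })
}

#' Generate a block-structured pair-energy matrix
#'
#' Within-domain entries are drawn around `-energy_block_strength`,
#' off-domain entries around 0; planted hotspot columns (and rows) are
#' shifted by `-hotspot_strength`; symmetric Gaussian noise of sd
#' `energy_noise_sd` is added; the diagonal is zero.
#'
#' @param spec a [synthetic_spec()].
#' @return a `pair_energy_matrix` with attribute `"ground_truth"`: list with
#'   `domain_labels` and `hotspot_columns`.
#' @export
gen_energy_matrix <- function(spec) {
  n <- spec$n_residues
  withr::with_seed(spec$seed, {
    dom <- domain_labels_of(spec)
    m <- matrix(0, n, n)
    same <- outer(dom, dom, `==`)
    m[same] <- -abs(spec$energy_block_strength)
    if (length(spec$hotspot_columns) > 0) {
      m[, spec$hotspot_columns] <- m[, spec$hotspot_columns] - abs(spec$hotspot_strength)
      m[spec$hotspot_columns, ] <- m[spec$hotspot_columns, ] - abs(spec$hotspot_strength)
      # the symmetric shift double-counts hotspot-hotspot pairs; keep them at
      # a single shift so all hotspot interactions share one magnitude
      hh <- spec$hotspot_columns
      m[hh, hh] <- m[hh, hh] + abs(spec$hotspot_strength)
    }
    if (spec$energy_noise_sd > 0) {
      noise <- matrix(0, n, n)
      up <- upper.tri(noise)
      noise[up] <- rnorm(sum(up), sd = spec$energy_noise_sd)
      noise <- noise + t(noise)
      m <- m + noise
    }
    diag(m) <- 0
    out <- as_pair_energy_matrix(m)
    attr(out, "ground_truth") <- list(domain_labels = dom,
                                      hotspot_columns = spec$hotspot_columns)
    out
  })
}

#' Write a generator's ground truth as a delimited sidecar
#'
#' @param x object carrying a `"ground_truth"` attribute.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(x, path) {
  gt <- attr(x, "ground_truth")
  if (is.null(gt)) abort("object carries no ground truth")
  flat <- lapply(gt, function(v) {
    if (is.list(v)) vapply(v, function(e) paste(signif(e, 8), collapse = ","), character(1))
    else paste(v, collapse = ",")
  })
  df <- tibble::tibble(key = names(flat),
                       value = vapply(flat, paste, character(1), collapse = ";"))
  readr::write_tsv(df, path)
  invisible(path)
}
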