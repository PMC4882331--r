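# Energy Decomposition Method (EDM).
#
# The N x N matrix M of average inter-residue nonbonded interaction energies
# is eigen-decomposed; the lowest (most negative) eigenvalues and their
# eigenvectors capture the attractive interactions stabilising the fold.
# For multidomain proteins a small set of "essential" eigenvectors is
# selected so that their significant components jointly cover the residues
# with minimal redundancy; the low-rank reconstruction from this set (the
# essential folding matrix) is symbolized to a binary contact-strength map
# whose connected components define energetic domains. Column sums of the
# interaction matrix give a per-residue stabilization profile whose
# below-average (more stabilizing) entries are the energetic hotspots.

#' Residue-pair nonbonded interaction-energy matrix
#'
#' `m_ij` is the frame average of the summed atom-pair Coulomb plus
#' Lennard-Jones energies between residues i and j:
#' `k_e q_a q_b / r_ab + 4 eps_ab ((sigma_ab/r_ab)^12 - (sigma_ab/r_ab)^6)`
#' with Lorentz-Berthelot combination rules
#' (`sigma_ab = (sigma_a + sigma_b)/2`, `eps_ab = sqrt(eps_a eps_b)`) and
#' `k_e = 332.0636 kcal A / (mol e^2)`. Intra-residue pairs are excluded
#' (zero diagonal); no cutoff is applied by default.
#'
#' @param coords `n_frames x n_atoms x 3` array (Angstrom) or a
#'   [trajectory()] whose positions are atoms.
#' @param params data frame with one row per atom, columns `residue`
#'   (1-based residue index), `charge` (e), `sigma` (Angstrom), `epsilon`
#'   (kcal/mol). Missing parameters raise an error.
#' @param residue_labels optional residue-label tibble of length
#'   `max(params$residue)`.
#' @param cutoff optional distance cutoff in Angstrom: atom pairs beyond it
#'   contribute zero. Its use is recorded in the `"cutoff"` attribute.
#' @return matrix of class `pair_energy_matrix` (`N x N`, kcal/mol), with
#'   attributes `frame_count` and `labels`.
#' @export
pair_energy_matrix <- function(coords, params, residue_labels = NULL, cutoff = NULL) {
  if (inherits(coords, "trajectory")) coords <- coords$coords
  if (is.matrix(coords)) coords <- array(coords, dim = c(1, dim(coords)))
  stopifnot(length(dim(coords)) == 3)
  n_atoms <- dim(coords)[2]
  params <- as.data.frame(params)
  req <- c("residue", "charge", "sigma", "epsilon")
  if (!all(req %in% names(params)))
    abort("params must have columns residue, charge, sigma, epsilon")
  if (nrow(params) != n_atoms)
    abort(sprintf("params has %d rows for %d atoms", nrow(params), n_atoms))
  if (anyNA(params[req]))
    abort(sprintf("atom(s) without parameters: %s",
                  paste(which(apply(is.na(params[req]), 1, any)), collapse = ", ")))
  res <- as.integer(params$residue)
  n_res <- max(res)
  if (!setequal(unique(res), seq_len(n_res)))
    abort("params$residue must use contiguous 1-based residue indices")
  q <- params$charge; sg <- params$sigma; ep <- params$epsilon
  qq <- KE_COULOMB * outer(q, q)
  sig_ab <- outer(sg, sg, function(a, b) (a + b) / 2)
  eps_ab <- sqrt(outer(ep, ep))
  same_res <- outer(res, res, `==`)
  n_frames <- dim(coords)[1]
  m_sum <- matrix(0, n_res, n_res)
  for (f in seq_len(n_frames)) {
    r <- as.matrix(dist(coords[f, , ]))
    zero_pair <- which(r == 0 & !diag(TRUE, n_atoms) & !same_res, arr.ind = TRUE)
    if (nrow(zero_pair) > 0)
      abort(sprintf("zero interatomic distance between atoms %d and %d in frame %d",
                    zero_pair[1, 1], zero_pair[1, 2], f))
    diag(r) <- Inf
    r[same_res] <- Inf   # intra-residue pairs excluded
    sr6 <- (sig_ab / r)^6
    e <- qq / r + 4 * eps_ab * (sr6^2 - sr6)
    if (!is.null(cutoff)) e[r > cutoff] <- 0
    e[!is.finite(e)] <- 0
    m_sum <- m_sum + rowsum(t(rowsum(e, res)), res)
  }
  m <- m_sum / n_frames
  diag(m) <- 0
  m <- (m + t(m)) / 2
  labels <- residue_labels %||% make_residue_labels("A", seq_len(n_res), resid = "GLY")
  dimnames(m) <- list(labels$label, labels$label)
  structure(m, class = c("pair_energy_matrix", "matrix", "array"),
            frame_count = n_frames, labels = labels, cutoff = cutoff)
}

as_pair_energy_matrix <- function(m, frame_count = 1L, labels = NULL) {
  n <- nrow(m)
  labels <- labels %||% make_residue_labels("A", seq_len(n), resid = "GLY")
  dimnames(m) <- list(labels$label, labels$label)
  structure(m, class = c("pair_energy_matrix", "matrix", "array"),
            frame_count = frame_count, labels = labels)
}

#' Eigen-decomposition of a pair interaction-energy matrix
#'
#' Full spectrum sorted ascending, so eigenvalue 1 is the most negative
#' (most stabilizing). Eigenvectors are unit norm with the
#' largest-magnitude-component-positive sign convention.
#'
#' @param m symmetric `N x N` energy matrix (kcal/mol); asymmetry beyond
#'   `1e-8` (relative to the largest entry) is an error.
#' @return object of class `edm_decomposition`: list with `values`,
#'   `vectors` (columns), `labels` and the input matrix `M`.
#' @export
edm_decompose <- function(m) {
  m <- unclass_matrix(m)
  if (!is.matrix(m) || nrow(m) != ncol(m)) abort("energy matrix must be square")
  scale <- max(abs(m), 1)
  if (max(abs(m - t(m))) > 1e-8 * scale) abort("energy matrix is not symmetric")
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE)
  ord <- order(ev$values)            # ascending: most negative first
  vals <- ev$values[ord]
  vecs <- ev$vectors[, ord, drop = FALSE]
  for (j in seq_len(ncol(vecs))) {
    if (vecs[which.max(abs(vecs[, j])), j] < 0) vecs[, j] <- -vecs[, j]
  }
  labels <- attr(m, "labels") %||%
    (if (!is.null(rownames(m))) tibble::tibble(label = rownames(m))
     else make_residue_labels("A", seq_len(nrow(m)), resid = "GLY"))
  structure(list(values = vals, vectors = vecs, labels = labels, M = m),
            class = "edm_decomposition")
}

unclass_matrix <- function(m) {
  lab <- attr(m, "labels")
  m <- unclass(m)
  attr(m, "frame_count") <- NULL
  attr(m, "cutoff") <- NULL
  if (!is.null(lab)) attr(m, "labels") <- lab
  m
}

#' Select the essential eigenvectors
#'
#' Greedy minimum-redundancy cover: a residue is "covered" by eigenvector k
#' when its component exceeds in magnitude the flat-vector reference
#' `1/sqrt(N)` (the value all components would take if every residue
#' contributed equally). Starting from the lowest eigenvector, eigenvectors
#' with negative eigenvalue are added in order of how many still-uncovered
#' residues they cover, skipping candidates whose significant set has
#' Jaccard overlap `>= jaccard_max` with the residues already covered, until
#' coverage reaches `coverage_target` or no candidate adds at least
#' `min_gain` residues (in which case a warning records the early stop).
#' Positive-eigenvalue (repulsive) eigenvectors are never selected.
#'
#' @param decomposition an [edm_decompose()] result.
#' @param coverage_target fraction of residues to cover (default 0.9).
#' @param min_gain minimum number of newly covered residues an eigenvector
#'   must add (default 5).
#' @param jaccard_max redundancy cap on the Jaccard overlap between a
#'   candidate's significant set and the covered set (default 0.25).
#' @return integer vector of selected eigenvector indices (ascending
#'   eigenvalue order), with attributes `coverage` (fraction covered) and
#'   `covered` (logical per residue).
#' @export
select_essential <- function(decomposition, coverage_target = 0.9,
                             min_gain = 5, jaccard_max = 0.25) {
  stopifnot(inherits(decomposition, "edm_decomposition"))
  n <- nrow(decomposition$vectors)
  thresh <- 1 / sqrt(n)
  sig <- abs(decomposition$vectors) > thresh   # n x n logical
  # only genuinely attractive (negative-eigenvalue) structure is selectable;
  # numerically-zero eigenvalues are excluded
  eig_tol <- 1e-10 * max(abs(decomposition$values), 1)
  candidates <- which(decomposition$values < -eig_tol)
  if (length(candidates) == 0) candidates <- 1L
  selected <- candidates[1]                     # always the lowest eigenvector
  covered <- sig[, selected]
  repeat {
    if (mean(covered) >= coverage_target) break
    remaining <- setdiff(candidates, selected)
    if (length(remaining) == 0) break
    gain <- vapply(remaining, function(k) sum(sig[, k] & !covered), integer(1))
    jac <- vapply(remaining, function(k) {
      u <- sum(sig[, k] | covered)
      if (u == 0) 0 else sum(sig[, k] & covered) / u
    }, numeric(1))
    ok <- jac < jaccard_max & gain >= min_gain
    if (!any(ok)) {
      if (mean(covered) < coverage_target)
        warn(sprintf("essential-set selection stopped by min_gain at coverage %.2f (target %.2f)",
                     mean(covered), coverage_target))
      break
    }
    best <- remaining[ok][which.max(gain[ok])]
    selected <- c(selected, best)
    covered <- covered | sig[, best]
  }
  structure(sort(selected), coverage = mean(covered), covered = covered)
}

#' Essential folding matrix
#'
#' Low-rank reconstruction `sum_k lambda_k v_k v_k^T` over the selected
#' essential eigenvectors; with the full spectrum this reproduces the input
#' matrix exactly.
#'
#' @param decomposition an [edm_decompose()] result.
#' @param essential_set integer eigenvector indices (e.g. from
#'   [select_essential()]).
#' @return `N x N` matrix (kcal/mol).
#' @export
folding_matrix <- function(decomposition, essential_set) {
  stopifnot(inherits(decomposition, "edm_decomposition"))
  if (length(essential_set) == 0) abort("essential_set must be non-empty")
  v <- decomposition$vectors[, essential_set, drop = FALSE]
  lam <- decomposition$values[essential_set]
  out <- v %*% (lam * t(v))
  dimnames(out) <- list(decomposition$labels$label, decomposition$labels$label)
  out
}

#' Symbolize a folding matrix
#'
#' Binarises the folding matrix to emphasise the significant attractive
#' interactions. Under the default `"mean-negative"` rule an entry is set
#' to 1 when it is at least as negative as the mean of the negative entries
#' (a matrix with no negative entry symbolizes to all zeros). The
#' alternative rule `"quantile:q"` thresholds at the q-th quantile of all
#' entries.
#'
#' @param folding numeric `N x N` folding (or energy) matrix.
#' @param rule `"mean-negative"` (default) or `"quantile:q"` with
#'   `q` in (0, 1), e.g. `"quantile:0.05"`.
#' @return binary `N x N` matrix (0/1) with the same dimnames.
#' @export
symbolize <- function(folding, rule = "mean-negative") {
  m <- unclass_matrix(folding)
  if (identical(rule, "mean-negative")) {
    neg <- m[m < 0]
    if (length(neg) == 0) return(m * 0)
    out <- (m <= mean(neg)) * 1
  } else if (grepl("^quantile:", rule)) {
    q <- suppressWarnings(as.numeric(sub("^quantile:", "", rule)))
    if (is.na(q) || q <= 0 || q >= 1) abort(sprintf("invalid quantile rule '%s'", rule))
    out <- (m < quantile(m, q)) * 1
  } else {
    abort(sprintf("unknown symbolization rule '%s'", rule))
  }
  dimnames(out) <- dimnames(m)
  out
}

#' Energetic domains from a symbolized matrix
#'
#' Residues are nodes; 1-entries are edges; connected components with at
#' least `min_size` residues become domains, numbered by ascending
#' first-residue index; smaller components are reported as "unassigned".
#' Note that two blocks joined by even a single spurious edge merge into one
#' component — the price of a deterministic, parameter-light clustering.
#'
#' @param symbolized symmetric binary matrix from [symbolize()].
#' @param min_size minimum component size to count as a domain (default 5).
#' @return character vector of per-residue domain ids ("1", "2", ... or
#'   "unassigned"), named by residue label when available.
#' @export
cluster_domains <- function(symbolized, min_size = 5) {
  m <- unclass_matrix(symbolized)
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  g <- igraph::graph_from_adjacency_matrix(m != 0, mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)
  out <- rep("unassigned", nrow(m))
  sizes <- comp$csize
  keep <- which(sizes >= min_size)
  if (length(keep) > 0) {
    first_res <- vapply(keep, function(k) min(which(comp$membership == k)), integer(1))
    keep <- keep[order(first_res)]
    for (d in seq_along(keep)) out[comp$membership == keep[d]] <- as.character(d)
  }
  names(out) <- rownames(m)
  out
}

#' Per-residue stabilization profile
#'
#' Column sums of the (folding or raw) interaction matrix: the contribution
#' of each residue to conformational stabilization. More negative = more
#' stabilizing.
#'
#' @param m square matrix (kcal/mol).
#' @return named numeric vector of length N.
#' @export
stabilization_profile <- function(m) {
  m <- unclass_matrix(m)
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  setNames(colSums(m), colnames(m))
}

#' Stabilization hotspots
#'
#' Residues whose stabilization value is strictly more negative than the
#' mean of all components.
#'
#' @param profile numeric per-residue stabilization vector.
#' @return integer indices of hotspot residues, named by residue label when
#'   the profile is named.
#' @export
select_hotspots <- function(profile) {
  idx <- which(profile < mean(profile))
  if (!is.null(names(profile))) idx <- setNames(idx, names(profile)[idx])
  idx
}

#' Full Energy Decomposition Method analysis
#'
#' Runs [edm_decompose()], [select_essential()], [folding_matrix()],
#' [symbolize()], [cluster_domains()], [stabilization_profile()] and
#' [select_hotspots()] with one call.
#'
#' @param m a `pair_energy_matrix` or plain symmetric energy matrix.
#' @inheritParams select_essential
#' @param symbolize_rule rule passed to [symbolize()].
#' @param min_domain_size passed to [cluster_domains()].
#' @param stabilization_on `"matrix"` (default: column sums of the raw
#'   matrix, as used for hotspot mapping) or `"folding"`.
#' @return object of class `edm_result`.
#' @export
edm <- function(m, coverage_target = 0.9, min_gain = 5, jaccard_max = 0.25,
                symbolize_rule = "mean-negative", min_domain_size = 5,
                stabilization_on = c("matrix", "folding")) {
  stabilization_on <- match.arg(stabilization_on)
  dec <- edm_decompose(m)
  ess <- select_essential(dec, coverage_target, min_gain, jaccard_max)
  fold <- folding_matrix(dec, ess)
  sym <- symbolize(fold, symbolize_rule)
  dom <- cluster_domains(sym, min_domain_size)
  stab <- stabilization_profile(if (stabilization_on == "matrix") dec$M else fold)
  hs <- select_hotspots(stab)
  structure(
    list(eigenvalues = dec$values, eigenvectors = dec$vectors,
         essential_set = as.integer(ess), coverage = attr(ess, "coverage"),
         folding = fold, symbolized = sym, domains = dom,
         stabilization = stab, hotspots = hs, labels = dec$labels,
         total_energy = sum(dec$M),
         params = list(coverage_target = coverage_target, min_gain = min_gain,
                       jaccard_max = jaccard_max, symbolize_rule = symbolize_rule,
                       min_domain_size = min_domain_size,
                       stabilization_on = stabilization_on)),
    class = "edm_result"
  )
}

#' @export
print.edm_result <- function(x, ...) {
  cat(sprintf("<edm_result> %d residues; %d essential eigenvectors (coverage %.2f); %d domains; %d hotspots\n",
              length(x$stabilization), length(x$essential_set), x$coverage,
              length(setdiff(unique(x$domains), "unassigned")), length(x$hotspots)))
  invisible(x)
}

#' @export
tidy.edm_result <- function(x, ...) {
  tibble::tibble(
    residue = x$labels$label,
    index = seq_along(x$domains),
    domain = x$domains,
    stabilization = unname(x$stabilization),
    hotspot = seq_along(x$domains) %in% x$hotspots
  )
}

#' @export
glance.edm_result <- function(x, ...) {
  tibble::tibble(
    n_residues = length(x$stabilization),
    n_essential = length(x$essential_set),
    coverage = x$coverage,
    n_domains = length(setdiff(unique(x$domains), "unassigned")),
    n_hotspots = length(x$hotspots),
    lambda1 = x$eigenvalues[1],
    total_energy = x$total_energy
  )
}

#' @export
autoplot.edm_result <- function(object, what = c("folding", "symbolized"), ...) {
  what <- match.arg(what)
  m <- if (what == "folding") object$folding else object$symbolized
  df <- tidyr::expand_grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  df$value <- m[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(name = "kcal/mol") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "residue i", y = "residue j") +
    ggplot2::theme_minimal()
}
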