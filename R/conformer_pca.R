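# Interconformer PCA: covariance of superposed Calpha coordinates,
# eigen-decomposition, and projection of structures / trajectory frames onto
# the leading principal components.

flatten_coords <- function(arr) {
  # m x N x 3 -> m x 3N, coordinate order (x1, y1, z1, x2, ...)
  m <- dim(arr)[1]
  t(vapply(seq_len(m), function(i) as.vector(t(arr[i, , ])), numeric(dim(arr)[2] * 3)))
}

#' Covariance matrix of superposed Cartesian coordinates
#'
#' Builds the `3N x 3N` population covariance (divide by the number of
#' conformers) of the flattened coordinates about the ensemble mean,
#' `C_ij = <(r_i - <r_i>)(r_j - <r_j>)>`, over all pairs of the 3N Cartesian
#' coordinates. Coordinates must already share a common frame
#' (see [iterative_mean_superpose()]).
#'
#' @param coords numeric array `m x N x 3` of superposed conformations, or an
#'   aligned [conformer_ensemble()].
#' @return symmetric positive-semidefinite `3N x 3N` matrix (Angstrom^2).
#' @export
build_covariance <- function(coords) {
  if (inherits(coords, "conformer_ensemble")) coords <- coords_array(coords)
  stopifnot(length(dim(coords)) == 3)
  m <- dim(coords)[1]
  if (m < 2) abort("at least 2 conformers are required for a covariance matrix")
  x <- flatten_coords(coords)
  xc <- sweep(x, 2, colMeans(x))
  crossprod(xc) / m
}

#' Principal components of a coordinate covariance matrix
#'
#' Diagonalises the covariance matrix and keeps the top `k` eigenpairs.
#' Variance fractions are eigenvalue / trace. The sign of each component is
#' fixed so that its largest-magnitude entry is positive, making projections
#' reproducible across linear-algebra backends.
#'
#' @param cov symmetric covariance matrix (`3N x 3N`).
#' @param k number of components to keep (default: all with positive
#'   eigenvalue, capped at 10). Asking for more components than the matrix
#'   rank returns trailing zero-eigenvalue components with a warning.
#' @param mean_coords optional `N x 3` ensemble mean, stored for projection.
#' @return an object of class `pca_model` with fields `mean_coords`,
#'   `components` (3N x k, orthonormal columns), `eigenvalues` (descending,
#'   Angstrom^2), `variance_fractions` and `trace`.
#' @export
fit_pca <- function(cov, k = NULL, mean_coords = NULL) {
  if (!is.matrix(cov) || nrow(cov) != ncol(cov)) abort("cov must be square")
  if (max(abs(cov - t(cov))) > 1e-8) abort("cov must be symmetric")
  ev <- eigen((cov + t(cov)) / 2, symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  tr <- sum(vals)
  rank <- sum(vals > max(vals[1], 1) * 1e-12)
  k <- k %||% max(1L, min(10L, rank))
  if (k > ncol(cov)) abort("k exceeds matrix dimension")
  if (k > rank)
    warn(sprintf("k = %d exceeds covariance rank %d; trailing components have zero eigenvalue", k, rank))
  comps <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (comps[which.max(abs(comps[, j])), j] < 0) comps[, j] <- -comps[, j]
  }
  structure(
    list(mean_coords = mean_coords,
         components = comps,
         eigenvalues = vals[seq_len(k)],
         variance_fractions = if (tr > 0) vals[seq_len(k)] / tr else rep(0, k),
         trace = tr),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components over %d coordinates\n",
              ncol(x$components), nrow(x$components)))
  vf <- round(100 * x$variance_fractions, 1)
  cat("  variance captured (%):", paste(vf, collapse = ", "), "\n")
  invisible(x)
}

#' Interconformer PCA of an aligned ensemble
#'
#' Convenience wrapper: iterative mean superposition, covariance build and
#' eigen-decomposition in one call.
#'
#' @param ensemble an aligned [conformer_ensemble()].
#' @inheritParams fit_pca
#' @return a `pca_model` carrying the converged ensemble mean.
#' @export
conformer_pca <- function(ensemble, k = NULL) {
  sup <- iterative_mean_superpose(ensemble)
  cov <- build_covariance(coords_array(sup))
  fit_pca(cov, k = k, mean_coords = attr(sup, "mean_coords"))
}

#' Project conformations onto principal components
#'
#' Each structure is first superposed onto the model's mean coordinates,
#' then its deviation from the mean is projected onto the components:
#' `score[i, j] = (r_i - r_mean) . v_j`. Projecting the mean structure gives
#' the zero vector.
#'
#' @param model a `pca_model` with `mean_coords` set.
#' @param coords `m x N x 3` array, `N x 3` matrix, [trajectory()] or aligned
#'   [conformer_ensemble()].
#' @param labels optional point labels (conformer ids / frame times are used
#'   when available).
#' @return a tibble of class `pca_projection` with columns `point` and
#'   `PC1..PCk` (Angstrom); variance fractions are kept as an attribute.
#' @export
project <- function(model, coords, labels = NULL) {
  stopifnot(inherits(model, "pca_model"))
  if (is.null(model$mean_coords)) abort("model has no mean_coords; fit with conformer_pca()")
  if (inherits(coords, "trajectory")) {
    labels <- labels %||% as.character(coords$times)
    coords <- coords$coords
  } else if (inherits(coords, "conformer_ensemble")) {
    labels <- labels %||% coords$ids
    coords <- coords_array(coords)
  } else if (is.matrix(coords)) {
    coords <- array(coords, dim = c(1, dim(coords)))
  }
  n_model <- nrow(model$components) / 3
  if (dim(coords)[2] != n_model)
    abort(sprintf("residue count mismatch: model has %d, coords have %d",
                  n_model, dim(coords)[2]))
  sup <- superpose(coords, model$mean_coords)
  x <- flatten_coords(sup$coords)
  dev <- sweep(x, 2, as.vector(t(model$mean_coords)))
  scores <- dev %*% model$components
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  out <- tibble::as_tibble(scores)
  out <- tibble::add_column(out, point = labels %||% as.character(seq_len(nrow(scores))),
                            .before = 1)
  class(out) <- c("pca_projection", class(out))
  attr(out, "variance_fractions") <- model$variance_fractions
  out
}

#' @export
tidy.pca_model <- function(x, ...) {
  tibble::tibble(
    component = paste0("PC", seq_along(x$eigenvalues)),
    eigenvalue = x$eigenvalues,
    variance_fraction = x$variance_fractions,
    cumulative_fraction = cumsum(x$variance_fractions)
  )
}

#' @export
glance.pca_model <- function(x, ...) {
  tibble::tibble(
    n_components = length(x$eigenvalues),
    total_variance = x$trace,
    pc1_fraction = x$variance_fractions[1],
    top2_fraction = sum(x$variance_fractions[seq_len(min(2, length(x$variance_fractions)))])
  )
}

#' @export
autoplot.pca_projection <- function(object, colour = NULL, ...) {
  vf <- attr(object, "variance_fractions")
  lab <- function(i) {
    if (!is.null(vf) && length(vf) >= i)
      sprintf("PC%d (%.1f%%)", i, 100 * vf[i]) else paste0("PC", i)
  }
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if (!is.null(colour)) {
    object$colour <- colour
    p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                              colour = .data$colour))
  }
  p + ggplot2::geom_point() +
    ggplot2::labs(x = lab(1), y = lab(2)) +
    ggplot2::theme_minimal()
}
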