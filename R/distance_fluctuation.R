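# Distance-fluctuation (coordination propensity) matrices and local
# flexibility profiles.
#
# A_ij is the time variance of the Calpha i-j distance: low values mark
# residue pairs moving as a rigid unit ("coordinated"); the matrix is
# invariant to rigid-body motion by construction, so no superposition is
# needed or performed.

#' Distance-fluctuation matrix of a trajectory
#'
#' `A_ij = <(d_ij - <d_ij>)^2>`, the population variance over frames of the
#' Calpha i-j distance; the time-average distances `<d_ij>` are returned
#' alongside.
#'
#' @param traj a [trajectory()] with at least 2 frames, or an
#'   `n_frames x N x 3` array.
#' @return an object of class `fluctuation_matrix`: list with `A`
#'   (`N x N`, Angstrom^2, zero diagonal), `mean_distances` (`N x N`,
#'   Angstrom), `n_frames` and the residue `labels`.
#' @export
fluctuation_matrix <- function(traj) {
  labels <- NULL
  if (inherits(traj, "trajectory")) {
    labels <- traj$labels
    coords <- traj$coords
  } else coords <- traj
  stopifnot(length(dim(coords)) == 3)
  nf <- dim(coords)[1]
  if (nf < 2) abort("at least 2 frames are required for distance fluctuations")
  n <- dim(coords)[2]
  d_sum <- matrix(0, n, n)
  d2_sum <- matrix(0, n, n)
  for (f in seq_len(nf)) {
    d <- as.matrix(dist(coords[f, , ]))
    d_sum <- d_sum + d
    d2_sum <- d2_sum + d^2
  }
  mean_d <- d_sum / nf
  a <- pmax(d2_sum / nf - mean_d^2, 0)
  diag(a) <- 0
  dimnames(a) <- dimnames(mean_d) <- NULL
  structure(list(A = a, mean_distances = mean_d, n_frames = nf,
                 labels = labels %||% make_residue_labels("A", seq_len(n), resid = "GLY")),
            class = "fluctuation_matrix")
}

#' @export
print.fluctuation_matrix <- function(x, ...) {
  cat(sprintf("<fluctuation_matrix> %d residues over %d frames; mean A = %.4g A^2\n",
              nrow(x$A), x$n_frames, mean(x$A[upper.tri(x$A)])))
  invisible(x)
}

#' Local flexibility profile
#'
#' `p(i) = sum_j A_ij f(<d_ij>)` with `j` restricted to the sequence window
#' `[i - window, i + window]`, `j != i`, truncated at the chain termini
#' (no wraparound). The distance weight `f` is `"uniform"` (`f = 1`, the
#' default) or `"inverse_square"` (`f(d) = 1/d^2`); the functional form of
#' `f` is a free choice of the statistic and is recorded in the output.
#'
#' @param fm a [fluctuation_matrix()].
#' @param window sequence half-width (default 4 residues).
#' @param weight_fn `"uniform"` or `"inverse_square"`.
#' @return a tibble of class `flexibility_profile` with columns `residue`
#'   (label), `index` and `p` (Angstrom^2); `window` and `weight_fn` kept as
#'   attributes.
#' @export
local_flexibility <- function(fm, window = 4, weight_fn = c("uniform", "inverse_square")) {
  stopifnot(inherits(fm, "fluctuation_matrix"))
  if (window < 1) abort("window must be >= 1")
  if (!is.character(weight_fn) || !(weight_fn[1] %in% c("uniform", "inverse_square")))
    abort(sprintf("unknown weight_fn '%s'", as.character(weight_fn[1])))
  weight_fn <- weight_fn[1]
  f <- switch(weight_fn,
              uniform = function(d) rep(1, length(d)),
              inverse_square = function(d) 1 / d^2)
  n <- nrow(fm$A)
  p <- vapply(seq_len(n), function(i) {
    j <- setdiff(max(1, i - window):min(n, i + window), i)
    sum(fm$A[i, j] * f(fm$mean_distances[i, j]))
  }, numeric(1))
  out <- tibble::tibble(residue = fm$labels$label, index = seq_len(n), p = p)
  class(out) <- c("flexibility_profile", class(out))
  attr(out, "window") <- window
  attr(out, "weight_fn") <- weight_fn
  out
}

#' Within- and between-domain mean distance fluctuation
#'
#' Averages `A` over the blocks defined by a per-residue domain labelling.
#' Self-pair blocks exclude the diagonal. Low within-domain means relative
#' to between-domain means indicate domains moving as rigid units.
#'
#' @param fm a [fluctuation_matrix()].
#' @param domains character (or factor) vector of per-residue domain labels,
#'   length `N`.
#' @return tibble with columns `domain_a`, `domain_b`, `mean_A`, `n_pairs`.
#' @export
block_coordination <- function(fm, domains) {
  stopifnot(inherits(fm, "fluctuation_matrix"))
  n <- nrow(fm$A)
  if (length(domains) != n)
    abort(sprintf("domain labels have length %d but the matrix has %d residues",
                  length(domains), n))
  domains <- as.character(domains)
  labs <- unique(domains)
  rows <- list()
  for (a in seq_along(labs)) for (b in a:length(labs)) {
    ia <- which(domains == labs[a]); ib <- which(domains == labs[b])
    block <- fm$A[ia, ib, drop = FALSE]
    if (a == b) {
      vals <- block[upper.tri(block)]
    } else {
      vals <- as.vector(block)
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      domain_a = labs[a], domain_b = labs[b],
      mean_A = if (length(vals)) mean(vals) else NA_real_,
      n_pairs = length(vals))
  }
  dplyr::bind_rows(rows)
}

#' @export
autoplot.fluctuation_matrix <- function(object, ...) {
  df <- tidyr::expand_grid(i = seq_len(nrow(object$A)), j = seq_len(ncol(object$A)))
  df$A <- object$A[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j, fill = .data$A)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = expression(A[ij] ~ (ring(A)^2)), direction = -1) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "residue i", y = "residue j") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.flexibility_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$index, y = .data$p)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue", y = expression(p(i) ~ (ring(A)^2))) +
    ggplot2::theme_minimal()
}

#' Write / read a residue matrix as labelled delimited text
#'
#' Tab-separated with residue labels as header row and first column; used
#' for fluctuation matrices, pair-energy matrices and folding matrices.
#'
#' @param m numeric matrix with residue labels.
#' @param labels character vector of residue labels (defaults to rownames).
#' @param path file path.
#' @return `read_matrix_tsv()` returns the matrix with labels as dimnames.
#' @export
write_matrix_tsv <- function(m, path, labels = NULL) {
  labels <- labels %||% rownames(m) %||% as.character(seq_len(nrow(m)))
  df <- as.data.frame(m)
  colnames(df) <- labels
  df <- cbind(residue = labels, df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  labels <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(labels, labels)
  m
}
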