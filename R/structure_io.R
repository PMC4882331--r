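# Containers and I/O for conformer ensembles and Calpha trajectories.
#
# Coordinates are Angstrom throughout. Residues are reported with their
# author (PDB) chain/number/insertion-code; internal indices are 1-based
# positions into the masked coordinate arrays.

# ---- residue labels ---------------------------------------------------------

make_residue_labels <- function(chain, resno, insert = NA_character_,
                                resid = NA_character_) {
  insert <- ifelse(is.na(insert) | insert == "", "", insert)
  tibble::tibble(
    chain = as.character(chain),
    resno = as.integer(resno),
    insert = as.character(insert),
    resid = as.character(resid),
    aa = three_to_one(resid),
    label = paste0(chain, ":", resno, insert)
  )
}

three_to_one <- function(resid) {
  out <- suppressWarnings(bio3d::aa321(resid))
  out[is.na(out) | out == ""] <- "X"
  out
}

# ---- ConformerEnsemble ------------------------------------------------------

#' Construct a conformer ensemble
#'
#' A `conformer_ensemble` holds a set of Calpha conformations of the same
#' (or homologous) protein: one coordinate matrix and one residue-label table
#' per conformer. Conformers may differ in length until [align_shared()] has
#' reduced them to the alignment-shared positions, after which all coordinate
#' matrices have equal row count and [coords_array()] returns the
#' `n_conformers x N x 3` array the downstream analyses consume.
#'
#' @param xyz list of `N_i x 3` numeric matrices (Angstrom), one per conformer.
#' @param labels list of residue-label tibbles (as built by the readers), one
#'   per conformer, each with `N_i` rows.
#' @param ids character vector of conformer identifiers.
#' @param shared_mask optional logical vector over the reference positions,
#'   recorded by [align_shared()].
#' @return an object of class `conformer_ensemble`.
#' @export
conformer_ensemble <- function(xyz, labels, ids = NULL, shared_mask = NULL) {
  stopifnot(is.list(xyz), is.list(labels), length(xyz) == length(labels))
  if (length(xyz) == 0) abort("empty ensemble")
  ids <- ids %||% paste0("conformer_", seq_along(xyz))
  for (i in seq_along(xyz)) {
    m <- xyz[[i]]
    if (!is.matrix(m) || ncol(m) != 3) abort("each conformer must be an N x 3 matrix")
    if (!all(is.finite(m))) abort(sprintf("non-finite coordinates in conformer '%s'", ids[i]))
    if (nrow(m) != nrow(labels[[i]])) abort("coordinate/label length mismatch")
  }
  ns <- vapply(xyz, nrow, integer(1))
  uniform <- length(unique(ns)) == 1L &&
    all(vapply(labels, function(l) identical(l$label, labels[[1]]$label), logical(1)))
  structure(
    list(
      xyz = xyz, labels = labels, ids = as.character(ids),
      uniform = uniform,
      residue_labels = if (uniform) labels[[1]] else NULL,
      shared_mask = shared_mask %||% if (uniform) rep(TRUE, ns[1]) else NULL
    ),
    class = "conformer_ensemble"
  )
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  ns <- vapply(x$xyz, nrow, integer(1))
  cat(sprintf("<conformer_ensemble> %d conformers, %s residues%s\n",
              length(x$xyz),
              if (x$uniform) as.character(ns[1]) else paste0(min(ns), "-", max(ns)),
              if (x$uniform) " (aligned)" else ""))
  invisible(x)
}

#' Number of conformers / residues in an ensemble
#' @param x a `conformer_ensemble`.
#' @return integer count.
#' @export
n_conformers <- function(x) length(x$xyz)

#' Coordinates of an aligned ensemble as a 3-d array
#'
#' @param x a `conformer_ensemble` whose conformers all have equal length
#'   (i.e. after [align_shared()], or built from equal-length inputs).
#' @return numeric array `n_conformers x N x 3`.
#' @export
coords_array <- function(x) {
  stopifnot(inherits(x, "conformer_ensemble"))
  ns <- vapply(x$xyz, nrow, integer(1))
  if (length(unique(ns)) != 1L)
    abort("conformers have unequal lengths; run align_shared() first")
  arr <- array(NA_real_, dim = c(length(x$xyz), ns[1], 3))
  for (i in seq_along(x$xyz)) arr[i, , ] <- x$xyz[[i]]
  arr
}

# ---- Trajectory -------------------------------------------------------------

#' Construct a Calpha trajectory
#'
#' @param coords numeric array `n_frames x N x 3` (Angstrom).
#' @param times numeric vector of frame times in ns, strictly increasing;
#'   defaults to `0, dt, 2*dt, ...` with `dt = 0.1` ns.
#' @param labels residue-label tibble with `N` rows (see
#'   [make_residue_labels()]); defaults to synthetic labels on chain "A".
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(coords, times = NULL, labels = NULL) {
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3)
    abort("coords must be an n_frames x N x 3 array")
  if (!all(is.finite(coords))) abort("non-finite coordinates")
  n_frames <- dim(coords)[1]
  n_res <- dim(coords)[2]
  times <- if (is.null(times)) (seq_len(n_frames) - 1) * 0.1 else as.numeric(times)
  if (length(times) != n_frames) abort("times length must equal n_frames")
  if (n_frames > 1 && any(diff(times) <= 0)) abort("frame times must be strictly increasing")
  labels <- labels %||% make_residue_labels("A", seq_len(n_res), resid = "GLY")
  if (nrow(labels) != n_res) abort("residue_labels length must equal N")
  structure(list(coords = coords, times = as.numeric(times), labels = labels),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d residues, %.4g-%.4g ns\n",
              dim(x$coords)[1], dim(x$coords)[2], min(x$times), max(x$times)))
  invisible(x)
}

#' @export
n_frames <- function(x) dim(x$coords)[1]

# ---- PDB reading ------------------------------------------------------------

#' Read conformer ensembles from PDB files
#'
#' Reads one conformer per MODEL per file, keeping Calpha atoms of the
#' selected chains only. Alternate locations are resolved to the highest
#' occupancy (ties broken by file order); insertion codes are kept as part of
#' the residue label.
#'
#' @param paths character vector of PDB file paths (single- or multi-model).
#' @param chain chain identifier(s) to keep; `NULL` keeps all chains, but the
#'   named chains must then be present in every file.
#' @return a [conformer_ensemble()].
#' @export
read_conformers <- function(paths, chain = NULL) {
  xyz <- list(); labels <- list(); ids <- character()
  for (path in paths) {
    if (!file.exists(path)) abort(sprintf("cannot read PDB file '%s'", path))
    pdb <- tryCatch(
      suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                       verbose = FALSE)),
      error = function(e) abort(sprintf("cannot read PDB file '%s': %s", path, conditionMessage(e)))
    )
    atom <- pdb$atom
    if (!is.null(chain)) {
      missing <- setdiff(chain, unique(atom$chain))
      if (length(missing) > 0)
        abort(sprintf("chain '%s' absent from file '%s'", paste(missing, collapse = ","), path))
      atom_idx <- which(atom$elety == "CA" & atom$chain %in% chain & atom$type == "ATOM")
    } else {
      atom_idx <- which(atom$elety == "CA" & atom$type == "ATOM")
    }
    if (length(atom_idx) == 0)
      abort(sprintf("no Calpha atoms found in file '%s'", path))
    sel <- resolve_altloc(atom[atom_idx, , drop = FALSE], atom_idx)
    lab <- make_residue_labels(atom$chain[sel], atom$resno[sel],
                               atom$insert[sel], atom$resid[sel])
    xyz_mat <- pdb$xyz
    if (is.null(dim(xyz_mat))) xyz_mat <- matrix(xyz_mat, nrow = 1)
    cols <- bio3d::atom2xyz(sel)
    for (m in seq_len(nrow(xyz_mat))) {
      crd <- matrix(xyz_mat[m, cols], ncol = 3, byrow = TRUE)
      if (!all(is.finite(crd)))
        abort(sprintf("non-finite coordinates in '%s' model %d", path, m))
      xyz <- c(xyz, list(crd))
      labels <- c(labels, list(lab))
      ids <- c(ids, paste0(sub("\\.pdb$", "", basename(path)),
                           if (nrow(xyz_mat) > 1) paste0("_m", m) else ""))
    }
  }
  conformer_ensemble(xyz, labels, ids)
}

# Highest-occupancy altloc per (chain, resno, insert); ties -> first in file.
resolve_altloc <- function(atoms, atom_idx) {
  key <- paste(atoms$chain, atoms$resno,
               ifelse(is.na(atoms$insert), "", atoms$insert), sep = "\r")
  occ <- atoms$o
  occ[is.na(occ)] <- 1
  keep <- integer(0)
  for (k in unique(key)) {
    rows <- which(key == k)
    keep <- c(keep, rows[which.max(occ[rows])])  # which.max: first on ties
  }
  atom_idx[sort(keep)]
}

#' Write an aligned ensemble to a multi-model PDB file
#'
#' @param ensemble an aligned [conformer_ensemble()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_conformers <- function(ensemble, path) {
  arr <- coords_array(ensemble)
  lab <- ensemble$residue_labels %||% ensemble$labels[[1]]
  n <- dim(arr)[2]
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_len(dim(arr)[1])) {
    writeLines(sprintf("MODEL     %4d", m), con)
    for (i in seq_len(n)) {
      writeLines(sprintf(
        "ATOM  %5d  CA  %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
        i, substr(lab$resid[i], 1, 3), lab$chain[i], lab$resno[i],
        ifelse(lab$insert[i] == "", " ", lab$insert[i]),
        arr[m, i, 1], arr[m, i, 2], arr[m, i, 3], 1, 0), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---- plain-text trajectory format ------------------------------------------

#' Read / write the plain-text trajectory format
#'
#' One frame per block of `N` lines "x y z", blocks separated by blank lines.
#' A sidecar file `<path>.meta.tsv` holds the residue labels and the frame
#' times (ns).
#'
#' @param path trajectory file path.
#' @return [read_trajectory()] returns a [trajectory()].
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) abort(sprintf("cannot read trajectory '%s'", path))
  lines <- readLines(path)
  blank <- grepl("^\\s*$", lines)
  grp <- cumsum(c(TRUE, diff(!blank) == 1) & !blank)
  grp[blank] <- 0L
  frames <- split(lines[!blank], grp[!blank])
  coords_list <- lapply(frames, function(fl) {
    m <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), as.numeric))
    if (ncol(m) != 3) abort("trajectory lines must hold three coordinates")
    m
  })
  n <- nrow(coords_list[[1]])
  arr <- array(NA_real_, dim = c(length(coords_list), n, 3))
  for (f in seq_along(coords_list)) arr[f, , ] <- coords_list[[f]]
  meta_path <- paste0(path, ".meta.tsv")
  times <- NULL; labels <- NULL
  if (file.exists(meta_path)) {
    meta <- readr::read_tsv(meta_path, show_col_types = FALSE, comment = "#",
                            col_types = readr::cols(insert = readr::col_character()))
    meta$insert[is.na(meta$insert)] <- ""
    labels <- make_residue_labels(meta$chain, meta$resno, meta$insert, meta$resid)
    tline <- grep("^# times_ns:", readLines(meta_path), value = TRUE)
    if (length(tline) == 1)
      times <- as.numeric(strsplit(sub("^# times_ns:\\s*", "", tline), "\\s+")[[1]])
  }
  trajectory(arr, times = times, labels = labels)
}

#' @rdname read_trajectory
#' @param traj a [trajectory()].
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  blocks <- apply(traj$coords, 1, function(fr) {
    paste(sprintf("%.6f %.6f %.6f", fr[, 1], fr[, 2], fr[, 3]), collapse = "\n")
  })
  writeLines(paste(blocks, collapse = "\n\n"), con)
  close(con)
  meta_path <- paste0(path, ".meta.tsv")
  con2 <- file(meta_path, "w")
  writeLines(paste0("# times_ns: ", paste(format(traj$times, digits = 10), collapse = " ")), con2)
  lab <- traj$labels
  writeLines("chain\tresno\tinsert\tresid", con2)
  writeLines(sprintf("%s\t%d\t%s\t%s", lab$chain, lab$resno, lab$insert, lab$resid), con2)
  close(con2)
  invisible(path)
}
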