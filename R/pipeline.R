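# End-to-end comparative analysis driven by a single declarative config.

config_defaults <- list(
  chain = NULL,
  k = 5,
  window = 4,
  weight_fn = "uniform",
  coverage_target = 0.9,
  min_gain = 5,
  jaccard_max = 0.25,
  symbolize_rule = "mean-negative",
  min_domain_size = 5,
  contact_cutoff = 8,
  flex_quantile = 0.9,
  seed = 1L
)

config_keys <- c("ensemble", "trajectories", "energy_matrices", "probe",
                 "difference_states", "out_dir", names(config_defaults))

#' Load and validate an analysis configuration
#'
#' The config is a YAML file (or a list) with keys: `ensemble`
#' (multi-model PDB path, optional), `chain`, `trajectories` (named map of
#' state label to plain-text trajectory path), `energy_matrices` (named map
#' of state label to labelled-TSV energy matrix), `probe` (two residue
#' labels), `difference_states` (two state labels whose flexibility profiles
#' are differenced, defaulting to the first two trajectory labels),
#' `out_dir`, `seed`, and the stage parameters `k`, `window`, `weight_fn`,
#' `coverage_target`, `min_gain`, `jaccard_max`, `symbolize_rule`,
#' `min_domain_size`, `contact_cutoff`, `flex_quantile`. Unknown keys are
#' rejected and every referenced path must exist.
#'
#' @param config path to a YAML file, or a named list.
#' @return validated config list of class `analysis_config` with all
#'   defaults filled in.
#' @export
analysis_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file '%s' does not exist", config))
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), config_keys)
  if (length(unknown) > 0)
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  for (key in names(config_defaults))
    if (is.null(config[[key]])) config[[key]] <- config_defaults[[key]]
  if (is.null(config$out_dir)) abort("config must set out_dir")
  for (p in c(config$ensemble, unlist(config$trajectories), unlist(config$energy_matrices)))
    if (!file.exists(p)) abort(sprintf("input path '%s' does not exist", p))
  if (!is.null(config$probe) && length(config$probe) != 2)
    abort("probe must name exactly two residues")
  structure(config, class = c("analysis_config", "list"))
}

#' Run the full comparative analysis
#'
#' Stages (each skipped when its inputs are absent from the config):
#' interconformer PCA of the ensemble; per state, projection of the
#' trajectory onto the ensemble PCs, distance-fluctuation matrix and local
#' flexibility profile, and probe-distance series; per state, the EDM on the
#' supplied energy matrix; finally the flexibility difference between the
#' two `difference_states` combined with both states' hotspots into the
#' regulatory-residue report. All outputs are delimited text under
#' `out_dir`, written atomically (a failed stage leaves no partial output),
#' plus a `manifest.yaml` recording every parameter — defaults included —
#' so a run is auditable and reproducible: identical config and inputs give
#' identical outputs.
#'
#' @param config an [analysis_config()] (or path / list coercible to one).
#' @return invisibly, a list with the in-memory results per stage.
#' @export
run_analysis <- function(config) {
  config <- analysis_config(config)
  staging <- tempfile("polconf_run_")
  dir.create(staging, recursive = TRUE)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)
  results <- list()
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  model <- NULL
  if (!is.null(config$ensemble)) {
    model <- stage("pca", {
      ens <- read_conformers(config$ensemble, chain = config$chain)
      if (n_conformers(ens) > 1) ens <- align_shared(ens)
      m <- conformer_pca(ens, k = config$k)
      readr::write_tsv(tidy(m), file.path(staging, "pca_variance.tsv"))
      sc <- project(m, iterative_mean_superpose(align_if_needed(ens)), labels = ens$ids)
      readr::write_tsv(tibble::as_tibble(sc), file.path(staging, "pca_ensemble_scores.tsv"))
      m
    })
    results$pca <- model
  }

  profiles <- list(); edms <- list(); trajs <- list()
  for (lab in names(config$trajectories)) {
    stage(paste0("trajectory:", lab), {
      traj <- read_trajectory(config$trajectories[[lab]])
      trajs[[lab]] <- traj
      if (!is.null(model)) {
        pr <- project(model, traj)
        readr::write_tsv(tibble::as_tibble(pr),
                         file.path(staging, paste0(lab, "_projection.tsv")))
      }
      fm <- fluctuation_matrix(traj)
      write_matrix_tsv(fm$A, file.path(staging, paste0(lab, "_fluctuation.tsv")),
                       labels = fm$labels$label)
      fp <- local_flexibility(fm, window = config$window, weight_fn = config$weight_fn)
      readr::write_tsv(tibble::as_tibble(fp),
                       file.path(staging, paste0(lab, "_flexibility.tsv")))
      profiles[[lab]] <- fp
      if (!is.null(config$probe)) {
        ps <- probe_distance_series(traj, config$probe[[1]], config$probe[[2]])
        out <- tibble::as_tibble(ps)
        readr::write_tsv(out, file.path(staging, paste0(lab, "_probe.tsv")))
      }
      NULL
    })
  }

  for (lab in names(config$energy_matrices)) {
    stage(paste0("edm:", lab), {
      m <- as_pair_energy_matrix(read_matrix_tsv(config$energy_matrices[[lab]]))
      res <- edm(m, coverage_target = config$coverage_target,
                 min_gain = config$min_gain, jaccard_max = config$jaccard_max,
                 symbolize_rule = config$symbolize_rule,
                 min_domain_size = config$min_domain_size)
      edms[[lab]] <- res
      readr::write_tsv(tidy(res), file.path(staging, paste0(lab, "_edm_residues.tsv")))
      write_matrix_tsv(res$folding, file.path(staging, paste0(lab, "_folding.tsv")),
                       labels = res$labels$label)
      NULL
    })
  }
  results$edm <- edms

  diff_states <- config$difference_states %||% utils::head(names(profiles), 2)
  if (length(diff_states) == 2 && all(diff_states %in% names(profiles)) &&
      length(edms) >= 1) {
    stage("hotspots", {
      dflex <- flexibility_difference(profiles[[diff_states[1]]],
                                      profiles[[diff_states[2]]])
      hs <- lapply(edms, function(e) e$hotspots)
      hs_a <- hs[[1]]
      hs_b <- if (length(hs) >= 2) hs[[2]] else integer(0)
      ref_traj <- trajs[[diff_states[1]]]
      mean_coords <- apply(ref_traj$coords, c(2, 3), mean)
      report <- combine_hotspots(hs_a, hs_b, dflex, mean_coords,
                                 contact_cutoff = config$contact_cutoff,
                                 flex_quantile = config$flex_quantile)
      readr::write_tsv(tibble::as_tibble(report),
                       file.path(staging, "regulatory_residues.tsv"))
      results$regulatory <- report
      NULL
    })
  }

  manifest <- config
  manifest$package_version <- as.character(utils::packageVersion("polconf"))
  class(manifest) <- "list"
  yaml::write_yaml(manifest, file.path(staging, "manifest.yaml"))

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (f in list.files(staging))
    file.copy(file.path(staging, f), file.path(config$out_dir, f), overwrite = TRUE)
  invisible(results)
}

align_if_needed <- function(ens) {
  if (ens$uniform) ens else align_shared(ens)
}
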