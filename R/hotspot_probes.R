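# Conformational-regulation residues and FRET-proxy probe distances.
#
# Energetic hotspots from two conformational states are intersected with the
# regions whose local flexibility differs most between the states: residues
# that both stabilize a conformation and touch a differentially flexible
# region are the ones whose mutation is most likely to perturb the
# open/closed equilibrium.

#' Difference of local flexibility profiles between two states
#'
#' `delta_p(i) = pA(i) - pB(i)`, e.g. closed minus open.
#'
#' @param pa,pb [local_flexibility()] profiles over the same residues.
#' @return tibble with columns `residue`, `index`, `p_a`, `p_b`, `delta_p`.
#' @export
flexibility_difference <- function(pa, pb) {
  if (nrow(pa) != nrow(pb) || !identical(pa$residue, pb$residue))
    abort("flexibility profiles have mismatching residue labels")
  tibble::tibble(residue = pa$residue, index = pa$index,
                 p_a = pa$p, p_b = pb$p, delta_p = pa$p - pb$p)
}

#' Nominate conformational-regulation residues
#'
#' A residue qualifies when (a) it is an energetic hotspot in at least one
#' state and (b) its Calpha lies within `contact_cutoff` of some residue
#' whose `|delta_p|` exceeds the `flex_quantile` quantile of all `|delta_p|`
#' values. Every reported residue therefore carries at least two evidence
#' flags (hotspot in state A and/or B, flexibility-difference contact).
#'
#' @param hotspots_a,hotspots_b integer residue indices (e.g. from
#'   [select_hotspots()]) for the two states.
#' @param delta_flex output of [flexibility_difference()] (or a numeric
#'   per-residue delta-p vector).
#' @param mean_coords `N x 3` Calpha coordinates used for contacts.
#' @param contact_cutoff Calpha-Calpha contact distance in Angstrom
#'   (default 8).
#' @param flex_quantile quantile of `|delta_p|` defining "significantly
#'   different flexibility" (default 0.9). Lowering it can only enlarge the
#'   reported set.
#' @param labels optional residue labels.
#' @return tibble of class `regulatory_report`: one row per qualifying
#'   residue with columns `residue`, `index`, `hotspot_a`, `hotspot_b`,
#'   `flex_contact`, `delta_p`, `min_contact_dist`; parameters recorded as
#'   attributes.
#' @export
combine_hotspots <- function(hotspots_a, hotspots_b, delta_flex, mean_coords,
                             contact_cutoff = 8, flex_quantile = 0.9,
                             labels = NULL) {
  if (contact_cutoff <= 0) abort("contact_cutoff must be positive")
  if (is.data.frame(delta_flex)) {
    labels <- labels %||% delta_flex$residue
    delta_p <- delta_flex$delta_p
  } else delta_p <- as.numeric(delta_flex)
  n <- length(delta_p)
  stopifnot(nrow(mean_coords) == n)
  labels <- labels %||% as.character(seq_len(n))
  hs_union <- sort(union(hotspots_a, hotspots_b))
  thresh <- quantile(abs(delta_p), flex_quantile, names = FALSE)
  flex_set <- which(abs(delta_p) > thresh)
  d <- as.matrix(dist(mean_coords))
  rows <- list()
  for (i in hs_union) {
    if (length(flex_set) == 0) break
    dmin <- min(d[i, flex_set])
    if (dmin <= contact_cutoff) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        residue = labels[i], index = i,
        hotspot_a = i %in% hotspots_a, hotspot_b = i %in% hotspots_b,
        flex_contact = TRUE, delta_p = delta_p[i], min_contact_dist = dmin)
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(residue = character(), index = integer(),
                   hotspot_a = logical(), hotspot_b = logical(),
                   flex_contact = logical(), delta_p = numeric(),
                   min_contact_dist = numeric())
  class(out) <- c("regulatory_report", class(out))
  attr(out, "contact_cutoff") <- contact_cutoff
  attr(out, "flex_quantile") <- flex_quantile
  out
}

#' FRET-proxy inter-residue distance time series
#'
#' Per-frame Calpha-Calpha distance between two labelled residues (e.g. the
#' fingers/thumb dye-attachment positions K498 and V692 of the Bst
#' polymerase), with an ordinary least-squares slope over time classifying
#' the trend as "closing" (negative slope), "opening" (positive) or
#' "stable".
#'
#' @param traj a [trajectory()].
#' @param res_a,res_b residue labels (`"chain:resno"`) or 1-based indices.
#' @return tibble of class `probe_series` with columns `time_ns` and
#'   `distance`; attributes `slope` (Angstrom/ns), `trend` and `residues`.
#' @export
probe_distance_series <- function(traj, res_a, res_b) {
  stopifnot(inherits(traj, "trajectory"))
  ia <- match_residue(traj$labels, res_a)
  ib <- match_residue(traj$labels, res_b)
  dvec <- sqrt(rowSums((traj$coords[, ia, ] - traj$coords[, ib, ])^2))
  slope <- if (length(dvec) > 1) unname(coef(lm(dvec ~ traj$times))[2]) else 0
  trend <- if (slope < -1e-8) "closing" else if (slope > 1e-8) "opening" else "stable"
  out <- tibble::tibble(time_ns = traj$times, distance = dvec)
  class(out) <- c("probe_series", class(out))
  attr(out, "slope") <- slope
  attr(out, "trend") <- trend
  attr(out, "residues") <- c(traj$labels$label[ia], traj$labels$label[ib])
  out
}

match_residue <- function(labels, res) {
  if (is.numeric(res)) {
    res <- as.integer(res)
    if (res < 1 || res > nrow(labels)) abort(sprintf("residue index %d out of range", res))
    return(res)
  }
  hit <- which(labels$label == res)
  if (length(hit) == 1) return(hit)
  near <- utils::head(labels$label[order(utils::adist(labels$label, res))], 3)
  abort(sprintf("unknown residue label '%s'; nearest matches: %s",
                res, paste(near, collapse = ", ")))
}

#' @export
autoplot.probe_series <- function(object, ...) {
  res <- attr(object, "residues")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ns, y = .data$distance)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "red") +
    ggplot2::labs(x = "time (ns)", y = "distance (Å)",
                  title = paste(res, collapse = " – ")) +
    ggplot2::theme_minimal()
}

#' @export
glance.probe_series <- function(x, ...) {
  tibble::tibble(
    n_frames = nrow(x),
    mean_distance = mean(x$distance),
    slope = attr(x, "slope"),
    trend = attr(x, "trend")
  )
}
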