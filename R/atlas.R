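#' Population probabilistic atlas
#'
#' For each network, the probability that a grayordinate is assigned to it is
#' the fraction of cohort participants who assigned it. Accepts a cohort of
#' single-assignment label maps (probability columns then sum to at most 1) or
#' of overlapping maps (columns may sum to more).
#'
#' @param cohort List of [label_map()]s or [overlap_map()]s sharing a space
#'   and palette.
#' @return A `probability_atlas`: `probs` (K-by-n_gray in \[0,1\]), `palette`,
#'   `n_participants`, `source_mode` (`"single_assignment"` or `"omni"`),
#'   `space`.
#' @export
probability_maps <- function(cohort) {
  if (length(cohort) < 1L) abort("Need at least one participant map.")
  first <- cohort[[1L]]
  pal <- first$palette
  K <- length(pal)
  n <- first$space$n_gray
  single <- inherits(first, "label_map")
  acc <- matrix(0, nrow = K, ncol = n, dimnames = list(pal, NULL))
  for (m in cohort) {
    if (!identical(m$palette, pal)) abort("Cohort palettes must match.")
    if (m$space$n_gray != n) abort("Cohort spaces must match.")
    if (inherits(m, "label_map")) {
      idx <- which(m$labels > 0L)
      acc[cbind(m$labels[idx], idx)] <- acc[cbind(m$labels[idx], idx)] + 1
    } else {
      acc <- acc + m$membership
    }
  }
  structure(list(probs = acc / length(cohort), palette = pal,
                 n_participants = length(cohort),
                 source_mode = if (single) "single_assignment" else "omni",
                 space = first$space),
            class = "probability_atlas")
}

#' @export
print.probability_atlas <- function(x, ...) {
  cat("<probability_atlas> ", nrow(x$probs), " networks x ", ncol(x$probs),
      " grayordinates (", x$source_mode, ", n = ", x$n_participants, ")\n",
      sep = "")
  invisible(x)
}

#' Derive a probabilistic ROI parcellation from an atlas
#'
#' For each network, thresholds the probability map at `p_threshold`, finds
#' connected components on the space adjacency (never spanning structure
#' boundaries), and drops components smaller than `min_cluster`. Parcel ids
#' are assigned network-major, then by descending size.
#'
#' @param atlas A `probability_atlas`.
#' @param p_threshold Probability threshold in (0, 1\] (default 0.8; 0.75 is
#'   the common consensus-map preset).
#' @param min_cluster Minimum parcel size in grayordinates (default 30).
#' @return A `parcellation`: tibble `parcels` (`parcel_id`, `network`,
#'   `size`), list `members` of grayordinate index vectors, `threshold`,
#'   `space`.
#' @export
derive_roiset <- function(atlas, p_threshold = 0.8, min_cluster = 30L) {
  if (p_threshold <= 0 || p_threshold > 1) abort("`p_threshold` must be in (0, 1].")
  parcels <- list()
  rows <- list()
  pid <- 0L
  for (k in seq_along(atlas$palette)) {
    members <- which(atlas$probs[k, ] >= p_threshold)
    comps <- space_components(atlas$space, members)
    comps <- comps[lengths(comps) >= min_cluster]
    for (comp in comps) {
      pid <- pid + 1L
      parcels[[pid]] <- comp
      rows[[pid]] <- tibble(parcel_id = pid, network = atlas$palette[k],
                            size = length(comp))
    }
  }
  if (pid == 0L) warn("Empty parcellation: no component survived the threshold.")
  structure(list(parcels = dplyr::bind_rows(rows), members = parcels,
                 threshold = p_threshold, space = atlas$space),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat("<parcellation> ", length(x$members), " parcels (threshold ",
      x$threshold, ")\n", sep = "")
  invisible(x)
}

#' Tidy a parcellation
#'
#' @param x A `parcellation`.
#' @param ... Unused.
#' @return The parcel tibble (`parcel_id`, `network`, `size`).
#' @export
tidy.parcellation <- function(x, ...) x$parcels

#' Integration zones from cohort overlap counts
#'
#' Averages per-participant network overlap counts across the cohort, then
#' thresholds the mean map (default at 2.2 networks) and keeps connected
#' components of at least `min_cluster` grayordinates as the integration-zone
#' region set.
#'
#' @param cohort List of [overlap_map()]s (or [scalar_map()]s of counts).
#' @param threshold Mean overlap count threshold (default 2.2).
#' @param min_cluster Minimum zone size (default 30).
#' @return An `integration_zones` object: `mean_count` ([scalar_map()]),
#'   `threshold`, and a `parcellation` of the zones (network name
#'   `"IntegrationZone"`).
#' @export
integration_zones <- function(cohort, threshold = 2.2, min_cluster = 30L) {
  if (length(cohort) < 1L) abort("Need at least one participant.")
  counts <- lapply(cohort, function(m) {
    if (inherits(m, "overlap_map")) colSums(m$membership) else m$values
  })
  mean_count <- Reduce(`+`, counts) / length(counts)
  space <- cohort[[1L]]$space
  members <- which(mean_count >= threshold)
  comps <- space_components(space, members)
  comps <- comps[lengths(comps) >= min_cluster]
  rows <- purrr::imap(comps, function(comp, i) {
    tibble(parcel_id = i, network = "IntegrationZone", size = length(comp))
  })
  parc <- structure(list(parcels = dplyr::bind_rows(rows), members = comps,
                         threshold = threshold, space = space),
                    class = "parcellation")
  structure(list(mean_count = scalar_map(mean_count, space, "mean_overlap_count"),
                 threshold = threshold, zones = parc),
            class = "integration_zones")
}

#' @export
print.integration_zones <- function(x, ...) {
  cat("<integration_zones> ", length(x$zones$members), " zones at threshold ",
      x$threshold, "\n", sep = "")
  invisible(x)
}

#' Parcel-averaged time series
#'
#' @param ts A [dense_timeseries()].
#' @param parcellation A `parcellation`.
#' @return T-by-n_parcels matrix (columns named `parcel_id`), the mean
#'   grayordinate series per parcel.
#' @export
parcellate_timeseries <- function(ts, parcellation) {
  if (length(parcellation$members) == 0L) abort("Parcellation is empty.")
  out <- vapply(parcellation$members,
                function(m) rowMeans(ts$values[, m, drop = FALSE]),
                numeric(nrow(ts$values)))
  colnames(out) <- as.character(parcellation$parcels$parcel_id)
  out
}

#' Parcellated connectivity matrix
#'
#' @param parcel_ts T-by-P parcel time-series matrix from
#'   [parcellate_timeseries()].
#' @param mask Optional [frame_mask()].
#' @return P-by-P Pearson correlation matrix.
#' @export
parcel_connectivity <- function(parcel_ts, mask = NULL) {
  v <- parcel_ts
  if (!is.null(mask)) v <- v[mask$retained, , drop = FALSE]
  if (nrow(v) < 3L) abort("Need at least 3 frames for parcel connectivity.")
  cor(v)
}

#' Within- and between-network connectivity statistics
#'
#' Averages the off-diagonal entries of a parcellated connectivity matrix over
#' parcel pairs within the same network, and over pairs spanning two
#' networks. Networks with a single parcel have no within-network pairs and
#' are reported as `NA`.
#'
#' @param pc P-by-P parcel connectivity matrix.
#' @param networks Character vector of network names per parcel (e.g.
#'   `parcellation$parcels$network`).
#' @return Tibble with columns `network_a`, `network_b`, `kind`
#'   (`"within"`/`"between"`), `mean_r`, `n_pairs`.
#' @export
network_block_stats <- function(pc, networks) {
  if (length(networks) != nrow(pc)) {
    abort("`networks` length must equal the parcel count.")
  }
  nets <- unique(networks)
  rows <- list()
  for (a in seq_along(nets)) {
    for (b in a:length(nets)) {
      ia <- which(networks == nets[a]); ib <- which(networks == nets[b])
      if (a == b) {
        if (length(ia) < 2L) {
          rows[[length(rows) + 1L]] <- tibble(
            network_a = nets[a], network_b = nets[b], kind = "within",
            mean_r = NA_real_, n_pairs = 0L)
          next
        }
        block <- pc[ia, ia]
        vals <- block[upper.tri(block)]
        kind <- "within"
      } else {
        vals <- as.numeric(pc[ia, ib])
        kind <- "between"
      }
      rows[[length(rows) + 1L]] <- tibble(
        network_a = nets[a], network_b = nets[b], kind = kind,
        mean_r = mean(vals), n_pairs = length(vals))
    }
  }
  dplyr::bind_rows(rows)
}
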