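#' Mean time series per network
#'
#' Averages a dense time series over the member grayordinates of each network
#' in a label map, per frame.
#'
#' @param ts A [dense_timeseries()].
#' @param labels A [label_map()] on the same space.
#' @return T-by-K numeric matrix, columns named by the palette.
#' @export
network_mean_timeseries <- function(ts, labels) {
  K <- length(labels$palette)
  out <- matrix(NA_real_, nrow = nrow(ts$values), ncol = K,
                dimnames = list(NULL, labels$palette))
  for (k in seq_len(K)) {
    members <- which(labels$labels == k)
    if (length(members) == 0L) {
      abort(paste0("Network '", labels$palette[k], "' has no member grayordinates."))
    }
    out[, k] <- rowMeans(ts$values[, members, drop = FALSE])
  }
  out
}

#' Per-participant network seed maps
#'
#' For each network of an initializing parcellation, correlates the network's
#' mean time series against every grayordinate, yielding a K-by-n_gray matrix
#' of seed correlations for one participant.
#'
#' @param ts A [dense_timeseries()].
#' @param labels Initializing [label_map()].
#' @param mask Optional [frame_mask()].
#' @return K-by-n_gray numeric matrix, rows named by the palette.
#' @export
participant_seed_maps <- function(ts, labels, mask = NULL) {
  means <- network_mean_timeseries(ts, labels)
  v <- ts$values
  if (!is.null(mask)) {
    v <- v[mask$retained, , drop = FALSE]
    means <- means[mask$retained, , drop = FALSE]
  }
  K <- ncol(means)
  out <- matrix(0, nrow = K, ncol = ncol(v),
                dimnames = list(colnames(means), NULL))
  for (k in seq_len(K)) {
    if (sd(means[, k]) == 0) {
      abort(paste0("Mean series of network '", colnames(means)[k],
                   "' has zero variance."))
    }
    r <- suppressWarnings(as.numeric(cor(means[, k], v)))
    r[is.na(r)] <- 0
    out[k, ] <- r
  }
  out
}

#' Build a network template set from a template cohort
#'
#' Seed-based correlation maps are averaged across the template participants
#' for each network separately; each averaged map is z-scored across
#' grayordinates and thresholded at z >= `z_cut` (default 1, keeping roughly
#' the top 15.9% of connections), giving a binary support per network.
#'
#' @param seed_map_list List of K-by-n_gray seed-map matrices, one per
#'   template participant (as from [participant_seed_maps()]).
#' @param palette Network names matching the rows.
#' @param z_cut Support threshold on the z-scored average map (default 1).
#' @return A `template_set`: `support` (K-by-n_gray binary), `zvalues`
#'   (K-by-n_gray z-scored average maps), `palette`, `n_participants`,
#'   `z_cut`.
#' @export
build_templates <- function(seed_map_list, palette = NULL, z_cut = 1) {
  if (length(seed_map_list) < 1L) abort("Need at least one template participant.")
  avg <- Reduce(`+`, seed_map_list) / length(seed_map_list)
  if (is.null(palette)) palette <- rownames(avg)
  if (is.null(palette)) abort("`palette` required when seed maps are unnamed.")
  K <- nrow(avg)
  z <- avg
  for (k in seq_len(K)) {
    s <- sd(avg[k, ])
    if (!is.finite(s) || s == 0) {
      abort(paste0("Average map for network '", palette[k],
                   "' is constant; cannot z-score."))
    }
    z[k, ] <- (avg[k, ] - mean(avg[k, ])) / s
  }
  support <- (z >= z_cut) * 1L
  if (any(rowSums(support) == 0L)) {
    abort("A template support is empty after thresholding.")
  }
  structure(list(support = support, zvalues = z, palette = as.character(palette),
                 n_participants = length(seed_map_list), z_cut = z_cut),
            class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat("<template_set> ", nrow(x$support), " networks x ", ncol(x$support),
      " grayordinates (z >= ", x$z_cut, "; built from ", x$n_participants,
      " participants)\n", sep = "")
  invisible(x)
}

#' Write / read a template set (plain text + JSON palette)
#'
#' @param templates A `template_set`.
#' @param path Output path; the z-value matrix is written as a K-row
#'   tab-delimited matrix with a JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_templates <- function(templates, path) {
  write_plain_matrix(templates$zvalues, path)
  jsonlite::write_json(
    list(palette = templates$palette, z_cut = templates$z_cut,
         n_participants = templates$n_participants),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_templates
#' @export
read_templates <- function(path) {
  meta <- read_sidecar(path)
  z <- read_plain_matrix(path)
  rownames(z) <- meta$palette
  support <- (z >= meta$z_cut) * 1L
  structure(list(support = support, zvalues = z, palette = meta$palette,
                 n_participants = meta$n_participants, z_cut = meta$z_cut),
            class = "template_set")
}
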