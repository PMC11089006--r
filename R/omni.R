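#' Histogram of eta-squared values for one network
#'
#' Values are distributed into 10,000 fixed-width bins on \[0, 1\] (so bin
#' indices 4,000-7,000 correspond to eta-squared 0.4-0.7) and a cubic-spline
#' interpolant of the counts, evaluated at bin centres, is stored as the
#' pre-smoothing curve. Values outside \[0, 1\] are clamped with a warning.
#'
#' @param values Numeric vector of eta-squared values for one network.
#' @param n_bins Number of bins (default 10,000).
#' @return An `eta_distribution`: `bin_edges` (n_bins + 1), `bin_centers`,
#'   `counts`, `curve` (cubic-spline fit at bin centres).
#' @export
eta_histogram <- function(values, n_bins = 10000L) {
  values <- as.numeric(values)
  if (any(values < 0 | values > 1)) {
    warn(sprintf("%d eta-squared value(s) outside [0, 1] clamped.",
                 sum(values < 0 | values > 1)))
    values <- pmin(pmax(values, 0), 1)
  }
  edges <- seq(0, 1, length.out = n_bins + 1L)
  centers <- (edges[-1L] + edges[-length(edges)]) / 2
  idx <- findInterval(values, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  fit <- spline(centers, counts, xout = centers, method = "fmm")
  structure(list(bin_edges = edges, bin_centers = centers,
                 counts = counts, curve = fit$y, n = length(values)),
            class = "eta_distribution")
}

#' @export
print.eta_distribution <- function(x, ...) {
  cat("<eta_distribution> ", length(x$counts), " bins over [0, 1], n = ",
      x$n, "\n", sep = "")
  invisible(x)
}

#' Tidy an eta distribution
#'
#' @param x An `eta_distribution`.
#' @param ... Unused.
#' @return Tibble with `bin`, `center`, `count`, `curve`.
#' @export
tidy.eta_distribution <- function(x, ...) {
  tibble(bin = seq_along(x$counts), center = x$bin_centers,
         count = x$counts, curve = x$curve)
}

# the Savitzky-Golay projection matrix is expensive to build; cache per (p, n)
.sg_cache <- new.env(parent = emptyenv())
sgolay_cached <- function(p, n) {
  key <- paste0(p, "_", n)
  if (is.null(.sg_cache[[key]])) .sg_cache[[key]] <- signal::sgolay(p = p, n = n)
  .sg_cache[[key]]
}

#' Data-driven bimodal threshold for one network
#'
#' The spline curve of the binned eta-squared distribution is smoothed with a
#' Savitzky-Golay filter (polynomial order `sg_order`, window `sg_window`
#' points; even windows are widened by one point since the filter needs an odd
#' window). The threshold is the local minimum between the two modes: the
#' first sign change (negative to positive) of the central-difference
#' derivative of the smoothed curve within the bin window (default bins
#' 4,000-7,000, i.e. eta-squared 0.4-0.7). If no sign change occurs, the
#' fallback is the argmin of the smoothed curve in the window.
#'
#' @param dist An `eta_distribution` from [eta_histogram()].
#' @param window Integer bin window to search (default `c(4000, 7000)`).
#' @param sg_window Savitzky-Golay window length in bins (default 2,000).
#' @param sg_order Savitzky-Golay polynomial order (default 3).
#' @return A `network_threshold` tibble row: `eta_star`, `bin_index`,
#'   `fallback_used`.
#' @export
find_bimodal_threshold <- function(dist, window = c(4000L, 7000L),
                                   sg_window = 2000L, sg_order = 3L) {
  n_bins <- length(dist$counts)
  sg_n <- as.integer(sg_window)
  if (sg_n %% 2L == 0L) sg_n <- sg_n + 1L
  sg_n <- min(sg_n, if (n_bins %% 2L == 0L) n_bins - 1L else n_bins)
  smoothed <- as.numeric(signal::sgolayfilt(dist$curve,
                                            sgolay_cached(sg_order, sg_n)))
  # central-difference derivative
  deriv <- c(NA_real_,
             (smoothed[-(1:2)] - smoothed[seq_len(length(smoothed) - 2L)]) / 2,
             NA_real_)
  lo <- max(2L, window[1L]); hi <- min(n_bins - 1L, window[2L])
  idx <- seq.int(lo, hi)
  d <- deriv[idx]
  sign_change <- which(d[-length(d)] < 0 & d[-1L] >= 0)
  # a genuine between-peak valley: the curve must rise appreciably on both
  # sides of the candidate over the FULL support (the modes themselves may
  # lie outside the search window), and the valley itself must be deep --
  # below half the peak height. The first qualifying derivative crossing in
  # the window is the threshold; filter ripple on a mode's flank fails the
  # depth guard, and micro-minima on a flat tail fail the rise guard.
  peak <- max(abs(smoothed))
  prom <- 0.01 * peak
  bin <- NA_integer_
  for (s in sign_change) {
    cand <- idx[s + 1L]
    if (smoothed[cand] > 0.5 * peak) next
    rise_left <- max(smoothed[1:cand]) - smoothed[cand]
    rise_right <- max(smoothed[cand:n_bins]) - smoothed[cand]
    if (rise_left > prom && rise_right > prom) { bin <- cand; break }
  }
  if (!is.na(bin)) {
    fallback <- FALSE
  } else {
    bin <- idx[which.min(smoothed[idx])]
    fallback <- TRUE
  }
  tibble(eta_star = dist$bin_centers[bin], bin_index = as.integer(bin),
         fallback_used = fallback)
}

#' Per-network OMNI thresholds for one participant
#'
#' Builds the 10,000-bin histogram of each network's eta-squared values and
#' locates the bimodal valley threshold for each.
#'
#' @param profile An `eta_profile` from [eta_profiles()].
#' @inheritParams find_bimodal_threshold
#' @return Tibble with one row per network: `network`, `eta_star`,
#'   `bin_index`, `fallback_used`.
#' @export
omni_thresholds <- function(profile, window = c(4000L, 7000L),
                            sg_window = 2000L, sg_order = 3L) {
  purrr::map_dfr(seq_len(nrow(profile$values)), function(k) {
    th <- find_bimodal_threshold(eta_histogram(profile$values[k, ]),
                                 window = window, sg_window = sg_window,
                                 sg_order = sg_order)
    dplyr::mutate(th, network = profile$palette[k], .before = 1L)
  })
}

#' OMNI multi-network assignment
#'
#' A grayordinate is assigned to every network whose eta-squared value exceeds
#' that network's threshold; grayordinates exceeding no threshold remain
#' unassigned.
#'
#' @param profile An `eta_profile`.
#' @param thresholds Tibble from [omni_thresholds()] (columns `network`,
#'   `eta_star`), or a named numeric vector of thresholds.
#' @param space A [gray_space()].
#' @return An [overlap_map()].
#' @export
omni_assign <- function(profile, thresholds, space) {
  if (is.data.frame(thresholds)) {
    th <- setNames(thresholds$eta_star, thresholds$network)
  } else {
    th <- thresholds
  }
  missing <- setdiff(profile$palette, names(th))
  if (length(missing) > 0L) {
    abort(paste0("Missing thresholds for: ", paste(missing, collapse = ", ")))
  }
  th <- th[profile$palette]
  membership <- (profile$values > th) * 1L
  overlap_map(membership, space, profile$palette)
}

#' Network overlap count per grayordinate
#'
#' @param om An [overlap_map()].
#' @return A [scalar_map()] of per-grayordinate membership counts.
#' @export
overlap_count <- function(om) {
  scalar_map(colSums(om$membership), om$space, name = "overlap_count")
}

#' OMNI overlapping-network map for one participant
#'
#' Convenience wrapper: dense correlation, block z-scoring, eta profiles,
#' per-network bimodal thresholds, multi-network assignment.
#'
#' @inheritParams template_match
#' @inheritParams find_bimodal_threshold
#' @return An [overlap_map()]; the threshold table is stored in
#'   `attr(, "thresholds")`.
#' @export
omni_map <- function(ts, templates, mask = NULL, z_cut = 1,
                     window = c(4000L, 7000L), sg_window = 2000L,
                     sg_order = 3L) {
  C <- blockwise_zscore(dense_correlation(ts, mask))
  prof <- eta_profiles(C, templates, z_cut = z_cut)
  th <- omni_thresholds(prof, window = window, sg_window = sg_window,
                        sg_order = sg_order)
  om <- omni_assign(prof, th, ts$space)
  attr(om, "thresholds") <- th
  om
}

#' Plot an eta-squared distribution with its threshold
#'
#' @param object An `eta_distribution`.
#' @param threshold Optional `network_threshold` row to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eta_distribution <- function(object, threshold = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$center, y = .data$count)) +
    ggplot2::geom_col(width = 1 / length(object$counts), fill = "grey60") +
    ggplot2::labs(x = expression(eta^2), y = "count")
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold$eta_star,
                                 linetype = "dashed", colour = "red")
  }
  p
}
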