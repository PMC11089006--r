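#' Dense grayordinate time series
#'
#' The universal input: a frames-by-grayordinates BOLD matrix with a
#' repetition time and a reference to its [gray_space()].
#'
#' @param values Numeric matrix, T frames by `space$n_gray` grayordinates.
#' @param space A [gray_space()].
#' @param tr_seconds Positive repetition time in seconds.
#' @return A `dense_timeseries` object.
#' @export
dense_timeseries <- function(values, space, tr_seconds) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2L) abort("A dense time series needs at least 2 frames.")
  if (!all(is.finite(values))) abort("Time-series values must all be finite.")
  if (ncol(values) != space$n_gray) {
    abort(sprintf("Column count (%d) must equal space$n_gray (%d).",
                  ncol(values), space$n_gray))
  }
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L ||
      !is.finite(tr_seconds) || tr_seconds <= 0) {
    abort("`tr_seconds` must be a single positive number.")
  }
  structure(list(values = values, space = space, tr_seconds = tr_seconds),
            class = "dense_timeseries")
}

#' @export
print.dense_timeseries <- function(x, ...) {
  cat("<dense_timeseries> ", nrow(x$values), " frames x ", ncol(x$values),
      " grayordinates, TR = ", x$tr_seconds, " s (",
      round(nrow(x$values) * x$tr_seconds / 60, 2), " min)\n", sep = "")
  invisible(x)
}

#' Per-grayordinate scalar map
#'
#' @param values Numeric vector of length `space$n_gray`.
#' @param space A [gray_space()].
#' @param name Map name.
#' @return A `scalar_map` object.
#' @export
scalar_map <- function(values, space, name = "map") {
  values <- as.numeric(values)
  if (length(values) != space$n_gray) {
    abort("Scalar map length must equal space$n_gray.")
  }
  structure(list(values = values, space = space, name = name),
            class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  cat("<scalar_map> '", x$name, "', ", length(x$values),
      " grayordinates, range [", signif(min(x$values), 4), ", ",
      signif(max(x$values), 4), "]\n", sep = "")
  invisible(x)
}

#' Single-assignment network label map
#'
#' Integer labels per grayordinate; 0 means unassigned. Labels index into an
#' ordered palette of network names.
#'
#' @param labels Integer vector of length `space$n_gray`, values in
#'   `0:length(palette)`.
#' @param space A [gray_space()].
#' @param palette Ordered unique network names (default the canonical 14).
#' @return A `label_map` object.
#' @export
label_map <- function(labels, space, palette = canonical_networks()) {
  labels <- as.integer(labels)
  if (length(labels) != space$n_gray) abort("Label length must equal space$n_gray.")
  if (anyNA(labels)) abort("Labels must not be NA.")
  if (anyDuplicated(palette)) abort("Palette names must be unique.")
  if (any(labels < 0L | labels > length(palette))) {
    abort(sprintf("Labels must lie in 0..%d (palette size).", length(palette)))
  }
  structure(list(labels = labels, space = space, palette = as.character(palette)),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat("<label_map> ", length(x$labels), " grayordinates, ",
      length(x$palette), "-network palette, ",
      sum(x$labels == 0L), " unassigned\n", sep = "")
  invisible(x)
}

#' Overlapping network membership map
#'
#' Binary K-by-n_gray membership matrix; a grayordinate may belong to any
#' number of networks, including none.
#'
#' @param membership Binary matrix, `length(palette)` rows by `space$n_gray`
#'   columns.
#' @param space A [gray_space()].
#' @param palette Ordered unique network names.
#' @return An `overlap_map` object.
#' @export
overlap_map <- function(membership, space, palette = canonical_networks()) {
  membership <- as.matrix(membership)
  storage.mode(membership) <- "integer"
  if (anyDuplicated(palette)) abort("Palette names must be unique.")
  if (nrow(membership) != length(palette)) {
    abort("Membership rows must equal palette length.")
  }
  if (ncol(membership) != space$n_gray) {
    abort("Membership columns must equal space$n_gray.")
  }
  if (!all(membership %in% c(0L, 1L))) abort("Membership entries must be 0/1.")
  rownames(membership) <- palette
  structure(list(membership = membership, space = space,
                 palette = as.character(palette)),
            class = "overlap_map")
}

#' @export
print.overlap_map <- function(x, ...) {
  cnt <- colSums(x$membership)
  cat("<overlap_map> ", ncol(x$membership), " grayordinates x ",
      nrow(x$membership), " networks; mean overlap ",
      round(mean(cnt), 3), ", ", sum(cnt == 0), " unassigned\n", sep = "")
  invisible(x)
}

#' Tidy a label map into a tibble
#'
#' @param x A `label_map`.
#' @param ... Unused.
#' @return Tibble with `grayordinate`, `structure`, `label`, `network`.
#' @export
tidy.label_map <- function(x, ...) {
  tibble(
    grayordinate = seq_along(x$labels),
    structure = x$space$structure,
    label = x$labels,
    network = ifelse(x$labels == 0L, NA_character_, x$palette[pmax(x$labels, 1L)])
  )
}

#' Tidy an overlap map into a long tibble of memberships
#'
#' @param x An `overlap_map`.
#' @param ... Unused.
#' @return Tibble with one row per (grayordinate, network) membership.
#' @export
tidy.overlap_map <- function(x, ...) {
  idx <- which(x$membership == 1L, arr.ind = TRUE)
  tibble(
    grayordinate = as.integer(idx[, 2L]),
    network = x$palette[idx[, 1L]]
  ) |> dplyr::arrange(.data$grayordinate, .data$network)
}
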