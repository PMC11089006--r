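#' Dense Pearson correlation matrix
#'
#' Correlates every grayordinate's time series with every other, over the
#' retained frames only.
#'
#' @param ts A [dense_timeseries()].
#' @param mask Optional [frame_mask()]; `NULL` uses all frames.
#' @return A `conn_matrix` object: symmetric `values` with unit diagonal,
#'   `normalized = "raw_r"`, and the space.
#' @export
dense_correlation <- function(ts, mask = NULL) {
  v <- ts$values
  if (!is.null(mask)) v <- v[mask$retained, , drop = FALSE]
  if (nrow(v) < 3L) abort("Need at least 3 retained frames for correlation.")
  sds <- apply(v, 2L, sd)
  if (any(sds == 0)) {
    abort(paste0("Zero-variance grayordinate(s) among retained frames: ",
                 paste(which(sds == 0), collapse = ", ")))
  }
  C <- cor(v)
  C <- (C + t(C)) / 2
  diag(C) <- 1
  conn_matrix(C, ts$space, normalized = "raw_r")
}

#' Connectivity matrix container
#'
#' @param values Symmetric n_gray-by-n_gray matrix.
#' @param space A [gray_space()].
#' @param normalized `"raw_r"` or `"block_z"`.
#' @return A `conn_matrix` object.
#' @export
conn_matrix <- function(values, space, normalized = c("raw_r", "block_z")) {
  normalized <- match.arg(normalized)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) abort("Connectivity matrix must be square.")
  if (nrow(values) != space$n_gray) abort("Matrix size must equal space$n_gray.")
  if (max(abs(values - t(values))) > 1e-10) abort("Matrix must be symmetric.")
  structure(list(values = values, space = space, normalized = normalized),
            class = "conn_matrix")
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat("<conn_matrix> ", nrow(x$values), " x ", ncol(x$values), " (",
      x$normalized, ")\n", sep = "")
  invisible(x)
}

# block ids over the full matrix from structure tags, as a compact integer
# matrix: 1 = LL, 2 = LR, 3 = RR (cortex within/between hemispheres),
# 4 = SS (subcortex), 5 = CS (cortex-subcortex)
block_names <- c("LL", "LR", "RR", "SS", "CS")

block_ids <- function(structure) {
  code <- ifelse(structure == "SUBCORTEX", 3L,
                 ifelse(structure == "LEFT_CORTEX", 1L, 2L))
  key <- outer(code, code, function(a, b) pmin(a, b) * 4L + pmax(a, b))
  # keys: 5 = LL, 6 = LR, 10 = RR, 15 = SS, 7/11 = CS
  map <- integer(15L)
  map[c(5L, 6L, 10L, 15L, 7L, 11L)] <- c(1L, 2L, 3L, 4L, 5L, 5L)
  matrix(map[key], nrow = length(code))
}

#' Block-wise z-scoring of a connectivity matrix
#'
#' The correlation matrix is z-scored separately within five blocks defined by
#' structure tags: left-hemisphere cortex (LL), right-hemisphere cortex (RR),
#' inter-hemispheric cortex (LR), subcortex (SS), and cortex-subcortex (CS).
#' This normalizes connectivity between regions of differing SNR (notably the
#' subcortex). Statistics are computed over off-diagonal entries; the diagonal
#' is set to zero in the normalized matrix.
#'
#' @param C A raw [conn_matrix()].
#' @return A [conn_matrix()] with `normalized = "block_z"`.
#' @export
blockwise_zscore <- function(C) {
  if (C$normalized != "raw_r") abort("Input must be a raw correlation matrix.")
  ids <- block_ids(C$space$structure)
  diag(ids) <- 0L  # diagonal excluded from block statistics
  v <- C$values
  out <- v
  for (b in setdiff(unique(as.integer(ids)), 0L)) {
    sel <- ids == b
    x <- v[sel]
    s <- sd(x)
    if (!is.finite(s) || s == 0) {
      abort(paste0("Constant block '", block_names[b], "' cannot be z-scored."))
    }
    out[sel] <- (x - mean(x)) / s
  }
  diag(out) <- 0
  out <- (out + t(out)) / 2
  conn_matrix(out, C$space, normalized = "block_z")
}

#' Seed-based correlation map
#'
#' Averages the time series of the seed grayordinates and correlates the mean
#' seed series with every grayordinate's series over the retained frames.
#'
#' @param ts A [dense_timeseries()].
#' @param seed Integer vector of seed grayordinate indices (non-empty).
#' @param mask Optional [frame_mask()].
#' @param name Map name.
#' @return A [scalar_map()] of correlations.
#' @export
seed_map <- function(ts, seed, mask = NULL, name = "seed") {
  seed <- as.integer(seed)
  if (length(seed) == 0L) abort("Seed set must be non-empty.")
  v <- ts$values
  if (!is.null(mask)) v <- v[mask$retained, , drop = FALSE]
  s <- rowMeans(v[, seed, drop = FALSE])
  if (sd(s) == 0) abort("Seed mean series has zero variance.")
  r <- suppressWarnings(as.numeric(cor(s, v)))
  r[is.na(r)] <- 0
  scalar_map(r, ts$space, name = name)
}

#' Zero short-distance connectivity
#'
#' Entries between grayordinates closer than `radius_mm` (Euclidean, in mm)
#' are set to zero, along with the diagonal, to avoid biasing community
#' detection toward spatially smoothed short-range connections.
#'
#' @param C A [conn_matrix()].
#' @param radius_mm Exclusion radius (default 30 mm).
#' @return A [conn_matrix()] with short-range entries zeroed.
#' @export
distance_exclude <- function(C, radius_mm = 30) {
  d <- as.matrix(stats::dist(C$space$coords))
  v <- C$values
  v[d < radius_mm] <- 0
  diag(v) <- 0
  conn_matrix(v, C$space, normalized = C$normalized)
}

#' Edge-density thresholding
#'
#' Retains the top `floor(density_percent/100 * n_pairs)` off-diagonal pairs
#' by (signed) weight, descending; ties are broken by index order. Returns an
#' undirected weighted edge list.
#'
#' @param C A [conn_matrix()].
#' @param density_percent Edge density in percent, in (0, 100].
#' @return Tibble with columns `i`, `j` (i < j) and `w`.
#' @export
density_threshold <- function(C, density_percent) {
  if (density_percent <= 0 || density_percent > 100) {
    abort("`density_percent` must lie in (0, 100].")
  }
  n <- nrow(C$values)
  ut <- which(upper.tri(C$values))
  k <- floor(density_percent / 100 * length(ut))
  if (k < 1L) {
    abort(sprintf("Density %.3g%% keeps no edges on %d pairs.",
                  density_percent, length(ut)))
  }
  w <- C$values[ut]
  ord <- order(-w, ut)
  sel <- ut[ord[seq_len(k)]]
  i <- ((sel - 1L) %% n) + 1L
  j <- ((sel - 1L) %/% n) + 1L
  tibble(i = as.integer(i), j = as.integer(j), w = C$values[sel]) |>
    dplyr::arrange(.data$i, .data$j)
}
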