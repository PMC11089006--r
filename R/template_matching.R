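#' Eta-squared similarity between two spatial profiles
#'
#' The Cohen-style image-similarity coefficient. With \eqn{m_i = (a_i+b_i)/2}
#' and \eqn{\bar M = \mathrm{mean}(m)}:
#' \deqn{\eta^2 = 1 - \frac{\sum_i (a_i - m_i)^2 + (b_i - m_i)^2}
#'                          {\sum_i (a_i - \bar M)^2 + (b_i - \bar M)^2}}
#' It equals 1 for identical non-constant profiles and 0 when all shared
#' variation is within-pair.
#'
#' @param a,b Numeric vectors of equal length (>= 2), not both constant.
#' @return A single value in \[0, 1\] (up to floating point).
#' @export
#' @examples
#' eta_squared(c(1, 2, 3), c(1, 2, 3))  # 1
#' eta_squared(c(1, 0), c(0, 1))        # 0
eta_squared <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  if (length(a) < 2L) abort("Profiles must have length >= 2.")
  m <- (a + b) / 2
  Mbar <- mean(m)
  num <- sum((a - m)^2 + (b - m)^2)
  den <- sum((a - Mbar)^2 + (b - Mbar)^2)
  if (den == 0) abort("eta-squared undefined: both profiles constant.")
  1 - num / den
}

# eta-squared between binary vectors from concordance counts.
# For a, b in {0,1}^n with counts c11, c10, c01, c00:
#   numerator  = (c10 + c01) / 2
#   M          = (c11 + (c10 + c01)/2) / n
#   denominator = 2 c11 (1-M)^2 + (c10 + c01)((1-M)^2 + M^2) + 2 c00 M^2
eta_squared_binary_counts <- function(c11, c10, c01, c00) {
  n <- c11 + c10 + c01 + c00
  disc <- c10 + c01
  num <- disc / 2
  M <- (c11 + disc / 2) / n
  den <- 2 * c11 * (1 - M)^2 + disc * ((1 - M)^2 + M^2) + 2 * c00 * M^2
  out <- 1 - num / den
  out[den == 0] <- NA_real_
  out
}

#' Eta-squared profiles of every grayordinate against every template
#'
#' Each grayordinate's row of the block-z-scored connectivity matrix is
#' binarized at z >= `z_cut` and compared (eta-squared over all grayordinates,
#' zeros included) with each network template's binary support.
#'
#' @param C A [conn_matrix()] with `normalized = "block_z"`.
#' @param templates A `template_set` from [build_templates()].
#' @param z_cut Binarization threshold (default 1).
#' @return An `eta_profile`: `values` (K-by-n_gray, in \[0,1\]), `palette`,
#'   `n_empty` (count of grayordinates whose binarized row was empty; their
#'   profile column is all zeros).
#' @export
eta_profiles <- function(C, templates, z_cut = 1) {
  if (C$normalized != "block_z") {
    abort("eta_profiles expects a block-z-scored connectivity matrix.")
  }
  if (ncol(templates$support) != C$space$n_gray) {
    abort("Templates and connectivity matrix must share the grayordinate space.")
  }
  B <- (C$values >= z_cut) * 1           # n_gray x n_gray binary rows
  S <- templates$support                 # K x n_gray
  n <- ncol(S)
  row_sums <- rowSums(B)                 # per grayordinate
  sup_sums <- rowSums(S)                 # per network
  c11 <- B %*% t(S)                      # n_gray x K
  c10 <- row_sums - c11
  c01 <- matrix(sup_sums, nrow = nrow(c11), ncol = ncol(c11), byrow = TRUE) - c11
  c00 <- n - c11 - c10 - c01
  vals <- eta_squared_binary_counts(c11, c10, c01, c00)
  vals <- t(vals)                        # K x n_gray
  empty <- row_sums == 0
  vals[, empty] <- 0
  vals[is.na(vals)] <- 0
  vals <- pmin(pmax(vals, 0), 1)
  rownames(vals) <- templates$palette
  structure(list(values = vals, palette = templates$palette,
                 z_cut = z_cut, n_empty = sum(empty)),
            class = "eta_profile")
}

#' @export
print.eta_profile <- function(x, ...) {
  cat("<eta_profile> ", nrow(x$values), " networks x ", ncol(x$values),
      " grayordinates (z_cut = ", x$z_cut, "; ", x$n_empty,
      " empty rows)\n", sep = "")
  invisible(x)
}

#' Winner-take-all network assignment
#'
#' Assigns each grayordinate to the network with the maximal eta-squared
#' value. All-zero profile columns stay unassigned (label 0); exact ties go to
#' the lowest palette index and are counted.
#'
#' @param profile An `eta_profile` from [eta_profiles()].
#' @param space A [gray_space()] for the resulting map.
#' @return A [label_map()]; the number of ties is stored in
#'   `attr(, "n_ties")`.
#' @export
winner_take_all <- function(profile, space) {
  v <- profile$values
  lab <- apply(v, 2L, which.max)         # lowest index on ties
  maxv <- apply(v, 2L, max)
  n_ties <- sum(apply(v, 2L, function(col) sum(col == max(col)) > 1L & max(col) > 0))
  lab[maxv <= 0] <- 0L
  out <- label_map(as.integer(lab), space, profile$palette)
  attr(out, "n_ties") <- n_ties
  out
}

#' Template-matching precision map for one participant
#'
#' Convenience wrapper: dense correlation (over retained frames), block-wise
#' z-scoring, eta-squared profiles against the templates, winner-take-all.
#'
#' @param ts A [dense_timeseries()].
#' @param templates A `template_set`.
#' @param mask Optional [frame_mask()].
#' @param z_cut Binarization threshold (default 1).
#' @return A [label_map()].
#' @export
template_match <- function(ts, templates, mask = NULL, z_cut = 1) {
  C <- blockwise_zscore(dense_correlation(ts, mask))
  winner_take_all(eta_profiles(C, templates, z_cut = z_cut), ts$space)
}
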