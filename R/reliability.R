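#' Normalized mutual information between two label maps
#'
#' Mutual information of the two labelings normalized by the arithmetic mean
#' of their entropies, computed over grayordinates assigned (label != 0) in
#' both maps. Identical partitions (up to relabeling) give 1. When either
#' partition has zero entropy, the result is 1 if the joint partition is
#' identical and 0 otherwise.
#'
#' @param A,B [label_map()]s on the same space (or plain integer vectors).
#' @return NMI in \[0, 1\].
#' @export
nmi <- function(A, B) {
  a <- if (inherits(A, "label_map")) A$labels else as.integer(A)
  b <- if (inherits(B, "label_map")) B$labels else as.integer(B)
  if (length(a) != length(b)) abort("Maps must share a space.")
  both <- a > 0L & b > 0L
  if (!any(both)) abort("No grayordinate is assigned in both maps.")
  a <- a[both]; b <- b[both]
  tab <- table(a, b)
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij); pj_ <- colSums(pij)
  hx <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  hy <- -sum(pj_[pj_ > 0] * log(pj_[pj_ > 0]))
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj_)[nz]))
  if (hx == 0 && hy == 0) return(1)
  if (hx == 0 || hy == 0) {
    # one side constant: identical iff the other is constant too
    return(0)
  }
  mi / ((hx + hy) / 2)
}

#' Split a frame set into interleaved or contiguous halves
#'
#' @param n_frames Total frame count.
#' @param mode `"interleaved"` (odd/even frames) or `"contiguous"`
#'   (first/second half).
#' @return List of two [frame_mask()]s.
#' @export
split_half_masks <- function(n_frames, mode = c("interleaved", "contiguous")) {
  mode <- match.arg(mode)
  idx <- seq_len(n_frames)
  if (mode == "interleaved") {
    h1 <- idx %% 2L == 1L
  } else {
    h1 <- idx <= n_frames %/% 2L
  }
  list(frame_mask(h1), frame_mask(!h1))
}

#' Split-half reliability of network maps
#'
#' Each participant's time series is split in half; a network map is computed
#' from each half by `map_fun`; the intra-participant NMI (half 1 vs half 2)
#' is compared against the null distribution of NMIs between halves of
#' different participants, with a one-tailed unequal-variance (Welch) t-test
#' of intra > null.
#'
#' @param cohort_ts List of [dense_timeseries()], one per participant.
#' @param map_fun Function `(ts, mask) -> label_map` producing a network map
#'   from one half.
#' @param mode Split mode, see [split_half_masks()].
#' @param seed Integer seed (kept for reproducibility of stochastic
#'   `map_fun`s; the split itself is deterministic).
#' @return A `split_half_result`: tibbles `intra` (participant, nmi) and
#'   `null` (participant_a, half_a, participant_b, half_b, nmi), plus
#'   `t_statistic`, `dof`, `p_value` (one-tailed, Welch).
#' @export
split_half <- function(cohort_ts, map_fun, mode = "interleaved", seed = 1L) {
  n <- length(cohort_ts)
  if (n < 2L) abort("Split-half reliability needs at least 2 participants.")
  set.seed(seed)
  halves <- lapply(cohort_ts, function(ts) {
    masks <- split_half_masks(nrow(ts$values), mode = mode)
    lapply(masks, function(m) map_fun(ts, m))
  })
  intra <- tibble(
    participant = seq_len(n),
    nmi = vapply(halves, function(h) nmi(h[[1L]], h[[2L]]), numeric(1L)))
  null_rows <- list()
  for (p in seq_len(n - 1L)) {
    for (q in seq.int(p + 1L, n)) {
      for (hp in 1:2) for (hq in 1:2) {
        null_rows[[length(null_rows) + 1L]] <- tibble(
          participant_a = p, half_a = hp, participant_b = q, half_b = hq,
          nmi = nmi(halves[[p]][[hp]], halves[[q]][[hq]]))
      }
    }
  }
  null <- dplyr::bind_rows(null_rows)
  tt <- t.test(intra$nmi, null$nmi, alternative = "greater", var.equal = FALSE)
  structure(list(intra = intra, null = null,
                 t_statistic = unname(tt$statistic), dof = unname(tt$parameter),
                 p_value = tt$p.value, tail = "one",
                 variance_assumption = "unequal"),
            class = "split_half_result")
}

#' @export
print.split_half_result <- function(x, ...) {
  cat("<split_half_result> mean intra NMI = ", round(mean(x$intra$nmi), 4),
      ", mean null NMI = ", round(mean(x$null$nmi), 4),
      "; Welch t(", round(x$dof, 2), ") = ", round(x$t_statistic, 3),
      ", one-tailed p = ", signif(x$p_value, 3), "\n", sep = "")
  invisible(x)
}

#' @rdname split_half
#' @param x A `split_half_result`.
#' @param ... Unused.
#' @export
glance.split_half_result <- function(x, ...) {
  tibble(mean_intra_nmi = mean(x$intra$nmi), mean_null_nmi = mean(x$null$nmi),
         t_statistic = x$t_statistic, dof = x$dof, p_value = x$p_value,
         n_participants = nrow(x$intra))
}

#' @rdname split_half
#' @export
tidy.split_half_result <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$intra, kind = "intra"),
    tibble(participant = x$null$participant_a, nmi = x$null$nmi, kind = "null"))
}

#' Plot split-half intra vs null NMI distributions
#'
#' @param object A `split_half_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.split_half_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nmi, fill = .data$kind)) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity", bins = 30) +
    ggplot2::labs(x = "NMI", y = "count", fill = NULL)
}

#' Edge-wise brain-behavior correlations
#'
#' Correlates every upper-triangle edge of the participants' connectivity
#' matrices with a behavioral score across participants.
#'
#' @param conn_list List of P-by-P connectivity matrices, one per participant.
#' @param behavior Numeric behavioral score per participant.
#' @return Numeric vector of Pearson correlations, one per upper-triangle
#'   edge (column-major order).
#' @export
brain_behavior_vector <- function(conn_list, behavior) {
  n <- length(conn_list)
  if (n < 4L) abort("Need at least 4 participants.")
  if (length(behavior) != n) abort("One behavioral score per participant required.")
  if (sd(behavior) == 0) abort("Behavioral scores have zero variance.")
  ut <- upper.tri(conn_list[[1L]])
  E <- vapply(conn_list, function(m) m[ut], numeric(sum(ut)))
  r <- suppressWarnings(as.numeric(cor(t(E), behavior)))
  r[is.na(r)] <- 0
  r
}

#' Subset reliability of brain-behavior associations
#'
#' Randomly samples participants from group 1 at each size (without
#' replacement, independently across replicates), computes the edge-wise
#' brain-behavior vector for the subsample, and correlates it with the
#' reference vector from group 2. The resulting (size, correlation) points
#' are fitted with the exponential rise-to-maximum curve.
#'
#' @param conn_list Group-1 connectivity matrices (list, one per participant).
#' @param behavior Group-1 behavioral scores.
#' @param reference Reference brain-behavior vector (e.g. from all of group
#'   2).
#' @param sizes Ascending subsample sizes (each >= 4, <= group-1 size).
#' @param reps Replicates per size (default 10).
#' @param seed Integer seed.
#' @return A `subset_reliability_curve`: tibble `samples` (`size`, `rep`,
#'   `correlation`), tibble `means`, and `fit` ([fit_rise_to_max()] result).
#' @export
subset_reliability <- function(conn_list, behavior, reference, sizes,
                               reps = 10L, seed = 1L) {
  n <- length(conn_list)
  if (any(sizes < 4L)) abort("All subsample sizes must be at least 4.")
  if (any(sizes > n)) abort("Subsample sizes cannot exceed the group size.")
  if (is.unsorted(sizes)) abort("`sizes` must be ascending.")
  set.seed(seed)
  rows <- list()
  for (s in sizes) {
    for (r in seq_len(reps)) {
      take <- sample.int(n, s)
      bb <- brain_behavior_vector(conn_list[take], behavior[take])
      rows[[length(rows) + 1L]] <- tibble(
        size = s, rep = r, correlation = cor(bb, reference))
    }
  }
  samples <- dplyr::bind_rows(rows)
  means <- samples |>
    dplyr::group_by(.data$size) |>
    dplyr::summarise(mean_correlation = mean(.data$correlation), .groups = "drop")
  fit <- fit_rise_to_max(samples$size, samples$correlation)
  structure(list(samples = samples, means = means, fit = fit),
            class = "subset_reliability_curve")
}

#' @export
print.subset_reliability_curve <- function(x, ...) {
  cat("<subset_reliability_curve> ", nrow(x$means), " sizes, ",
      nrow(x$samples), " samples; fit r^2 = ", round(x$fit$r_squared, 4),
      "\n", sep = "")
  invisible(x)
}

#' @rdname subset_reliability
#' @param x A `subset_reliability_curve`.
#' @param ... Unused.
#' @export
tidy.subset_reliability_curve <- function(x, ...) x$samples

#' @rdname subset_reliability
#' @export
glance.subset_reliability_curve <- function(x, ...) glance(x$fit)

#' Plot a subset reliability curve with its rise-to-maximum fit
#'
#' @param object A `subset_reliability_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.subset_reliability_curve <- function(object, ...) {
  f <- object$fit
  xs <- seq(min(object$samples$size), max(object$samples$size), length.out = 200)
  pred <- tibble(size = xs,
                 correlation = f$y0 + f$a * (1 - exp(-f$b * xs)))
  ggplot2::ggplot(object$samples,
                  ggplot2::aes(x = .data$size, y = .data$correlation)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_line(data = pred, colour = "blue") +
    ggplot2::labs(x = "subsample size", y = "intergroup correlation")
}

#' Exponential rise-to-maximum fit
#'
#' Fits \eqn{y = y_0 + a (1 - e^{-bx})} by nonlinear least squares
#' (Levenberg-Marquardt), with \eqn{b \ge 0}. A constant response is detected
#' up front and returned as a degenerate fit with `a = 0`.
#'
#' @param x Sample sizes (>= 3 distinct values, >= 4 points).
#' @param y Correlations.
#' @return A `rise_fit`: `y0`, `a`, `b`, `r_squared`, `degenerate`.
#' @export
fit_rise_to_max <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 4L) abort("Need at least 4 points.")
  if (length(unique(x)) < 3L) abort("Need at least 3 distinct x values.")
  if (sd(y) < 1e-12) {
    return(structure(list(y0 = mean(y), a = 0, b = 0, r_squared = 1,
                          degenerate = TRUE), class = "rise_fit"))
  }
  y0_init <- min(y)
  a_init <- max(y) - min(y)
  if (a_init <= 0) a_init <- sd(y)
  b_init <- 1 / stats::median(x)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ y0 + a * (1 - exp(-b * x)),
      start = list(y0 = y0_init, a = a_init, b = b_init),
      lower = c(y0 = -Inf, a = -Inf, b = 0),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) abort(paste0("Rise-to-maximum fit failed: ",
                                     conditionMessage(e))))
  cf <- coef(fit)
  ss_res <- sum(resid(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(y0 = unname(cf["y0"]), a = unname(cf["a"]), b = unname(cf["b"]),
                 r_squared = 1 - ss_res / ss_tot, degenerate = FALSE),
            class = "rise_fit")
}

#' @export
print.rise_fit <- function(x, ...) {
  cat("<rise_fit> y0 = ", signif(x$y0, 5), ", a = ", signif(x$a, 5),
      ", b = ", signif(x$b, 5), ", r^2 = ", round(x$r_squared, 4),
      if (x$degenerate) " (degenerate)", "\n", sep = "")
  invisible(x)
}

#' @rdname fit_rise_to_max
#' @param x A `rise_fit`.
#' @param ... Unused.
#' @export
tidy.rise_fit <- function(x, ...) {
  tibble(term = c("y0", "a", "b"), estimate = c(x$y0, x$a, x$b))
}

#' @rdname fit_rise_to_max
#' @export
glance.rise_fit <- function(x, ...) {
  tibble(y0 = x$y0, a = x$a, b = x$b, r_squared = x$r_squared,
         degenerate = x$degenerate)
}
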