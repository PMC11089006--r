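#' Framewise displacement from rigid-body motion parameters
#'
#' FD for frame i is the sum of absolute frame-to-frame changes in the three
#' translations (mm) plus the three rotations, with rotations converted from
#' degrees to millimetres of arc length on a sphere of `radius_mm`
#' (approximately the mean distance from cortex to the head centre):
#' \deqn{FD_i = |\Delta p_{ix}| + |\Delta p_{iy}| + |\Delta p_{iz}| +
#'       r(|\Delta \alpha_i| + |\Delta \beta_i| + |\Delta \gamma_i|)}
#' The first frame has no predecessor, so `FD[1] = 0`.
#'
#' @param trace Numeric matrix or data frame with 6 columns: translations
#'   x, y, z in mm, then rotations in degrees. One row per frame.
#' @param radius_mm Sphere radius for rotation conversion (default 50).
#' @return Tibble with columns `frame` and `fd_mm`.
#' @export
compute_fd <- function(trace, radius_mm = 50) {
  trace <- as.matrix(trace)
  if (ncol(trace) != 6L) abort("Motion trace must have 6 columns.")
  if (!all(is.finite(trace))) abort("Motion parameters must be finite.")
  if (!is.finite(radius_mm) || radius_mm < 0) abort("`radius_mm` must be finite and non-negative.")
  tn <- nrow(trace)
  fd <- numeric(tn)
  if (tn > 1L) {
    d <- abs(diff(trace))
    fd[-1L] <- rowSums(d[, 1:3, drop = FALSE]) +
      radius_mm * rowSums(d[, 4:6, drop = FALSE] * pi / 180)
  }
  tibble(frame = seq_len(tn), fd_mm = fd)
}

#' Censoring configuration
#'
#' @param fd_threshold_mm FD above which a frame is censored (default 0.2 mm).
#' @param min_segment_frames Minimum length of a surviving run of retained
#'   frames; shorter runs are censored too (default 5).
#' @param sphere_radius_mm Rotation conversion radius for FD (default 50).
#' @param mad_k Multiplier for the scaled-MAD BOLD outlier rule (default 3).
#' @return A `censor_config` list.
#' @export
censor_config <- function(fd_threshold_mm = 0.2, min_segment_frames = 5L,
                          sphere_radius_mm = 50, mad_k = 3) {
  vals <- c(fd_threshold_mm, min_segment_frames, sphere_radius_mm, mad_k)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("All censoring parameters must be positive and finite.")
  }
  structure(list(fd_threshold_mm = fd_threshold_mm,
                 min_segment_frames = as.integer(min_segment_frames),
                 sphere_radius_mm = sphere_radius_mm, mad_k = mad_k),
            class = "censor_config")
}

#' Censor frames by FD, short segments, and BOLD outliers
#'
#' Frames with FD above the threshold are censored; then any surviving run of
#' contiguous retained frames shorter than `min_segment_frames` is censored;
#' finally, if per-frame BOLD spatial standard deviations are supplied, frames
#' whose s.d. deviates from the median of the retained frames by more than
#' `mad_k` scaled MADs (1.4826 consistency constant) are censored.
#'
#' @param fd Numeric FD vector (mm) or the tibble from [compute_fd()].
#' @param cfg A [censor_config()].
#' @param bold_sd Optional per-frame spatial standard deviation of the BOLD
#'   signal, used for the median-absolute-deviation outlier rule.
#' @return A `frame_mask` object: logical `retained`, counts and diagnostics
#'   (`n_fd_censored`, `n_segment_censored`, `n_mad_censored`).
#' @export
censor_frames <- function(fd, cfg = censor_config(), bold_sd = NULL) {
  if (is.data.frame(fd)) fd <- fd$fd_mm
  fd <- as.numeric(fd)
  tn <- length(fd)
  keep <- fd <= cfg$fd_threshold_mm
  n_fd <- sum(!keep)
  # censor retained runs shorter than the minimum segment length
  r <- rle(keep)
  short <- r$values & r$lengths < cfg$min_segment_frames
  n_seg <- sum(r$lengths[short])
  r$values[short] <- FALSE
  keep <- inverse.rle(r)
  n_mad <- 0L
  if (!is.null(bold_sd)) {
    bold_sd <- as.numeric(bold_sd)
    if (length(bold_sd) != tn) abort("`bold_sd` length must match the FD series.")
    if (any(keep)) {
      s <- bold_sd[keep]
      med <- median(s)
      scaled_mad <- mad(s, center = med)  # includes the 1.4826 constant
      out <- keep & abs(bold_sd - med) > cfg$mad_k * scaled_mad
      n_mad <- sum(out)
      keep[out] <- FALSE
    }
  }
  frame_mask(keep, n_fd_censored = n_fd, n_segment_censored = n_seg,
             n_mad_censored = n_mad)
}

#' Frame retention mask
#'
#' @param retained Logical vector, TRUE = frame kept.
#' @param ... Named diagnostic counters stored alongside.
#' @return A `frame_mask` object.
#' @export
frame_mask <- function(retained, ...) {
  retained <- as.logical(retained)
  if (anyNA(retained)) abort("Mask entries must be TRUE/FALSE.")
  structure(list(retained = retained, retained_count = sum(retained), ...),
            class = "frame_mask")
}

#' @export
print.frame_mask <- function(x, ...) {
  cat("<frame_mask> ", x$retained_count, "/", length(x$retained),
      " frames retained\n", sep = "")
  invisible(x)
}

#' Minutes of data retained by a mask
#'
#' @param mask A [frame_mask()].
#' @param tr_seconds Repetition time in seconds.
#' @return Retained minutes.
#' @export
retained_minutes <- function(mask, tr_seconds) {
  mask$retained_count * tr_seconds / 60
}

#' Randomly sample retained frames to an exact duration
#'
#' Selects a uniformly random subset of the retained frames amounting to
#' exactly `minutes` of data (`round(minutes * 60 / tr_seconds)` frames), so
#' that every participant contributes the same scan duration to downstream
#' correlation matrices.
#'
#' @param mask A [frame_mask()].
#' @param tr_seconds Repetition time in seconds.
#' @param minutes Target duration in minutes.
#' @param seed Integer seed; the same seed reproduces the same subset.
#' @return A [frame_mask()] whose retained set is a subset of `mask`.
#' @export
sample_exact_duration <- function(mask, tr_seconds, minutes, seed) {
  n_need <- round(minutes * 60 / tr_seconds)
  avail <- which(mask$retained)
  if (length(avail) < n_need) {
    abort(sprintf(
      "Insufficient retained frames: need %d (%.2f min at TR %.3g s), have %d (shortfall %d).",
      n_need, minutes, tr_seconds, length(avail), n_need - length(avail)))
  }
  keep <- logical(length(mask$retained))
  set.seed(seed)
  keep[sort(sample(avail, n_need))] <- TRUE
  frame_mask(keep, sampled_minutes = minutes)
}

#' Nuisance regression of a dense time series
#'
#' Removes, by ordinary least squares, the design consisting of an intercept,
#' the three tissue mean signals (whole brain, ventricle, white matter), the
#' six rigid-body motion parameters, the first differences of all nine
#' regressors, and the squares of all eighteen preceding columns. The full
#' (uncensored) series is regressed; censoring masks are applied later when
#' correlations are formed.
#'
#' @param ts A [dense_timeseries()].
#' @param trace T-by-6 motion parameter matrix.
#' @param tissue_means Data frame / list with numeric elements `whole_brain`,
#'   `ventricle`, `white_matter`, each of length T.
#' @return A [dense_timeseries()] of residuals.
#' @export
regress_nuisance <- function(ts, trace, tissue_means) {
  tn <- nrow(ts$values)
  trace <- as.matrix(trace)
  need <- c("whole_brain", "ventricle", "white_matter")
  if (!all(need %in% names(tissue_means))) {
    abort("`tissue_means` must contain whole_brain, ventricle, white_matter.")
  }
  base <- cbind(tissue_means$whole_brain, tissue_means$ventricle,
                tissue_means$white_matter, trace)
  if (nrow(base) != tn) abort("Nuisance regressor length must match the time series.")
  d1 <- rbind(0, diff(base))
  X18 <- cbind(base, d1)
  design <- cbind(1, X18, X18^2)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- ncol(design) - qrd$rank
    warn(sprintf("Rank-deficient nuisance design: dropped %d collinear column(s).",
                 dropped))
  }
  res <- qr.resid(qrd, ts$values)
  dense_timeseries(res, ts$space, ts$tr_seconds)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a first-order Butterworth band-pass (default 0.009-0.080 Hz) once
#' forward and once backward (MATLAB `filtfilt` convention), giving zero phase
#' shift and the squared magnitude response.
#'
#' @param ts A [dense_timeseries()].
#' @param low_hz,high_hz Pass-band edges in Hz.
#' @return A filtered [dense_timeseries()].
#' @export
bandpass <- function(ts, low_hz = 0.009, high_hz = 0.080) {
  fs <- 1 / ts$tr_seconds
  nyq <- fs / 2
  if (low_hz <= 0 || high_hz >= nyq || low_hz >= high_hz) {
    abort(sprintf("Band (%.4g, %.4g) Hz must lie inside (0, Nyquist = %.4g).",
                  low_hz, high_hz, nyq))
  }
  bf <- signal::butter(1, c(low_hz, high_hz) / nyq, type = "pass")
  out <- apply(ts$values, 2L, function(col) signal::filtfilt(bf, col))
  dense_timeseries(out, ts$space, ts$tr_seconds)
}

#' Read / write a motion trace (6-column tab-delimited text)
#'
#' @param path File path; one frame per row, translations (mm) then rotations
#'   (degrees).
#' @return T-by-6 numeric matrix.
#' @export
read_motion <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  m <- read_plain_matrix(path)
  if (ncol(m) != 6L) abort("Motion trace file must have 6 columns.")
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  m
}

#' @rdname read_motion
#' @param trace T-by-6 motion parameter matrix.
#' @export
write_motion <- function(trace, path) {
  write_plain_matrix(as.matrix(trace), path)
  invisible(path)
}
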