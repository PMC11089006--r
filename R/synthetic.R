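# Synthetic multi-participant cohort with planted network topographies.
# The generator is the ground-truth oracle for the mapping methods: K
# networks are planted as nearest-centre partitions of a two-cap cortical +
# interior subcortical geometry, each participant's topography is jittered,
# designated hub zones mix several networks, BOLD arises from band-limited
# latent network signals plus noise at a configurable SNR, and motion traces
# carry censorable spikes.

#' Build a synthetic grayordinate space
#'
#' Cortical grayordinates are placed uniformly on two mirrored hemispheric
#' caps of a 70 mm sphere; subcortical grayordinates fill an interior ball of
#' 25 mm radius. A symmetrized 6-nearest-neighbour adjacency is built.
#'
#' @param n_gray Total grayordinate count (>= 100).
#' @param fractions Length-3 fractions (left cortex, right cortex,
#'   subcortex), summing to 1. Left and right are balanced to allow exact
#'   mirroring.
#' @param seed Integer seed.
#' @return A [gray_space()].
#' @export
make_space <- function(n_gray, fractions = c(0.4, 0.4, 0.2), seed = 1L) {
  if (n_gray < 100L) abort("`n_gray` must be at least 100.")
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    abort("`fractions` must be 3 non-negative values summing to 1.")
  }
  n_sub <- round(n_gray * fractions[3L])
  n_left <- (n_gray - n_sub) %/% 2L
  n_right <- n_gray - n_sub - n_left
  set.seed(seed)
  # uniform directions on the unit sphere
  sphere <- function(n) {
    z <- runif(n, -1, 1)
    th <- runif(n, 0, 2 * pi)
    r <- sqrt(1 - z^2)
    cbind(r * cos(th), r * sin(th), z)
  }
  n_half <- max(n_left, n_right)
  left <- sphere(n_half) * 70
  left[, 1L] <- -abs(left[, 1L]) - 1  # keep off the midline
  right <- left[seq_len(n_right), , drop = FALSE]
  right[, 1L] <- -right[, 1L]
  left <- left[seq_len(n_left), , drop = FALSE]
  sub <- sphere(n_sub) * (25 * runif(n_sub)^(1 / 3))
  coords <- rbind(left, right, sub)
  structure_tags <- c(rep("LEFT_CORTEX", n_left), rep("RIGHT_CORTEX", n_right),
                      rep("SUBCORTEX", n_sub))
  gray_space(coords, structure_tags)
}

# deterministic, well-balanced cortical centres: farthest-point seeding
# followed by Lloyd iterations (centroids snapped back to the cortical
# surface), so planted networks have comparable territory sizes
group_centers <- function(space, K, lloyd_iter = 15L) {
  cortex <- which(space$structure != "SUBCORTEX")
  cc <- space$coords[cortex, , drop = FALSE]
  centers <- cortex[1L]
  d <- sqrt(rowSums((cc - matrix(space$coords[centers, ], nrow = length(cortex),
                                 ncol = 3L, byrow = TRUE))^2))
  while (length(centers) < K) {
    nxt <- cortex[which.max(d)]
    centers <- c(centers, nxt)
    dn <- sqrt(rowSums((cc - matrix(space$coords[nxt, ], nrow = length(cortex),
                                    ncol = 3L, byrow = TRUE))^2))
    d <- pmin(d, dn)
  }
  ctr <- space$coords[centers, , drop = FALSE]
  for (it in seq_len(lloyd_iter)) {
    part <- nearest_center(cc, ctr)
    new_ctr <- ctr
    for (k in seq_len(K)) {
      members <- which(part == k)
      if (length(members) == 0L) next
      centroid <- colMeans(cc[members, , drop = FALSE])
      # snap to the nearest cortical grayordinate to stay on the caps
      snap <- members[which.min(colSums((t(cc[members, , drop = FALSE]) -
                                           centroid)^2))]
      new_ctr[k, ] <- cc[snap, ]
    }
    if (max(abs(new_ctr - ctr)) < 1e-9) break
    ctr <- new_ctr
  }
  ctr
}

nearest_center <- function(coords, centers) {
  d2 <- outer(rowSums(coords^2), rep(1, nrow(centers))) -
    2 * coords %*% t(centers) +
    outer(rep(1, nrow(coords)), rowSums(centers^2))
  max.col(-d2, ties.method = "first")
}

#' Designate hub (overlap) zones at group partition boundaries
#'
#' Hub centres are the grayordinates where the two nearest network centres are
#' most nearly equidistant (partition boundaries), greedily spaced at least
#' `2 * radius_mm` apart. Each zone comprises the grayordinates within
#' `radius_mm` of its centre; its member networks are the
#' `networks_per_hub` nearest group centres.
#'
#' @param space A [gray_space()].
#' @param centers K-by-3 group network centre coordinates.
#' @param n_hubs Number of zones.
#' @param radius_mm Zone radius.
#' @param networks_per_hub Number of member networks per zone.
#' @return List with `mask` (logical per grayordinate), `zones` (list of
#'   index vectors) and `networks` (list of member network index vectors).
#' @export
place_hubs <- function(space, centers, n_hubs = 3L, radius_mm = 10,
                       networks_per_hub = 2L) {
  coords <- space$coords
  d2 <- outer(rowSums(coords^2), rep(1, nrow(centers))) -
    2 * coords %*% t(centers) +
    outer(rep(1, nrow(coords)), rowSums(centers^2))
  sorted <- t(apply(d2, 1L, sort))
  margin <- sqrt(pmax(sorted[, 2L], 0)) - sqrt(pmax(sorted[, 1L], 0))
  cortex <- space$structure != "SUBCORTEX"
  ord <- order(margin + ifelse(cortex, 0, Inf))
  hub_centers <- integer(0)
  for (g in ord) {
    if (length(hub_centers) >= n_hubs) break
    if (length(hub_centers) > 0L) {
      dmin <- min(sqrt(rowSums((coords[hub_centers, , drop = FALSE] -
                                  matrix(coords[g, ], nrow = length(hub_centers),
                                         ncol = 3L, byrow = TRUE))^2)))
      if (dmin < 2 * radius_mm) next
    }
    hub_centers <- c(hub_centers, g)
  }
  zones <- lapply(hub_centers, function(h) {
    which(sqrt(rowSums((coords - matrix(coords[h, ], nrow = nrow(coords),
                                        ncol = 3L, byrow = TRUE))^2)) <= radius_mm)
  })
  networks <- lapply(hub_centers, function(h) {
    order(d2[h, ])[seq_len(networks_per_hub)]
  })
  mask <- logical(space$n_gray)
  mask[unlist(zones)] <- TRUE
  list(mask = mask, zones = zones, networks = networks)
}

#' Plant per-participant network memberships
#'
#' The group partition assigns each grayordinate to its nearest of K network
#' centres. Per participant, the centres are jittered by isotropic Gaussian
#' noise (sd `jitter_sigma_mm` per axis) and the partition recomputed; a
#' membership weight matrix W (n_gray x K) is one-hot from the jittered
#' partition except inside hub zones, where the zone's member networks share
#' weight 1/m each. Truth labels are the argmax of W (lowest index on hub
#' ties); the overlap truth is the support of W.
#'
#' @param space A [gray_space()].
#' @param K Number of networks (>= 2).
#' @param jitter_sigma_mm Per-axis topographic jitter (mm).
#' @param hubs Hub specification from [place_hubs()], or `NULL`.
#' @param participant_seed Integer seed.
#' @param centers Optional K-by-3 centre matrix; default from the space via
#'   farthest-point sampling (deterministic).
#' @param palette Network names (default first K canonical names).
#' @return List with `W`, `labels` ([label_map()]), `overlap`
#'   ([overlap_map()]), `centers`.
#' @export
plant_networks <- function(space, K, jitter_sigma_mm = 0, hubs = NULL,
                           participant_seed = 1L, centers = NULL,
                           palette = canonical_networks()[seq_len(K)]) {
  if (K < 2L) abort("Need at least 2 networks.")
  if (is.null(centers)) centers <- group_centers(space, K)
  set.seed(participant_seed)
  part <- NULL
  for (try in 1:20) {
    jit <- centers + matrix(rnorm(3L * K, sd = jitter_sigma_mm), ncol = 3L)
    part <- nearest_center(space$coords, jit)
    if (length(unique(part)) == K) break
    if (try == 20L) {
      warn("A network stayed empty after jitter; reseeding produced no fix.")
    } else if (try > 1L) {
      warn("Empty network after jitter; reseeding.")
    }
  }
  W <- matrix(0, nrow = space$n_gray, ncol = K)
  W[cbind(seq_len(space$n_gray), part)] <- 1
  if (!is.null(hubs)) {
    for (z in seq_along(hubs$zones)) {
      members <- hubs$networks[[z]]
      W[hubs$zones[[z]], ] <- 0
      W[hubs$zones[[z]], members] <- 1 / length(members)
    }
  }
  labels <- label_map(max.col(W, ties.method = "first"), space, palette)
  overlap <- overlap_map(t(W > 0) * 1L, space, palette)
  list(W = W, labels = labels, overlap = overlap, centers = centers)
}

#' Simulate BOLD from planted memberships
#'
#' K latent network signals are white Gaussian series band-limited to the
#' analysis band (0.009-0.08 Hz) and standardized; each grayordinate's signal
#' mixes its (L2-normalized) membership row, plus iid Gaussian noise with
#' standard deviation `1/snr` (snr = network-signal sd / noise sd).
#'
#' @param W n_gray-by-K membership weight matrix.
#' @param space A [gray_space()].
#' @param n_frames Frame count.
#' @param tr_seconds Repetition time (s).
#' @param snr Signal-to-noise ratio (> 0).
#' @param seed Integer seed.
#' @return A [dense_timeseries()].
#' @export
simulate_bold <- function(W, space, n_frames, tr_seconds = 0.8, snr = 4,
                          seed = 1L) {
  if (snr <= 0) abort("`snr` must be positive.")
  K <- ncol(W)
  set.seed(seed)
  fs <- 1 / tr_seconds
  bf <- signal::butter(1, c(0.009, 0.080) / (fs / 2), type = "pass")
  S <- matrix(rnorm(n_frames * K), nrow = n_frames, ncol = K)
  S <- apply(S, 2L, function(col) {
    f <- signal::filtfilt(bf, col)
    f / sd(f)
  })
  norms <- sqrt(rowSums(W^2))
  norms[norms == 0] <- 1
  Wn <- W / norms
  X <- S %*% t(Wn) + matrix(rnorm(n_frames * nrow(W), sd = 1 / snr),
                            nrow = n_frames)
  dense_timeseries(X, space, tr_seconds)
}

#' Simulate a rigid-body motion trace
#'
#' Baseline motion is a random walk with small parameter increments scaled so
#' typical framewise displacement sits near 0.02 mm; spike frames (Bernoulli
#' `spike_prob`) add `amplitude` mm to one translation for a single frame,
#' producing censorable FD excursions on that frame and the next.
#'
#' @param n_frames Frame count.
#' @param spike_prob Per-frame spike probability.
#' @param amplitude Spike amplitude in mm (default 0.5).
#' @param seed Integer seed.
#' @return T-by-6 motion parameter matrix (mm, degrees); spike frames in
#'   `attr(, "spike_frames")`.
#' @export
simulate_motion <- function(n_frames, spike_prob = 0.02, amplitude = 0.5,
                            seed = 1L) {
  set.seed(seed)
  sd_trans <- 0.005                       # mm per-axis increment
  sd_rot <- 0.005 * 180 / (50 * pi)       # FD-equivalent degrees
  inc <- cbind(matrix(rnorm(n_frames * 3L, sd = sd_trans), ncol = 3L),
               matrix(rnorm(n_frames * 3L, sd = sd_rot), ncol = 3L))
  inc[1L, ] <- 0
  trace <- apply(inc, 2L, cumsum)
  spikes <- which(runif(n_frames) < spike_prob)
  spikes <- setdiff(spikes, 1L)
  if (length(spikes) > 1L) spikes <- spikes[c(TRUE, diff(spikes) > 1L)]
  for (s in spikes) {
    axis <- sample.int(3L, 1L)
    trace[s, axis] <- trace[s, axis] + amplitude
  }
  colnames(trace) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  attr(trace, "spike_frames") <- spikes
  trace
}

#' Simulate behavioral scores from connectivity features
#'
#' @param features Participants-by-edges feature matrix.
#' @param effects Tibble with `edge` (column index) and `beta`.
#' @param noise_sd Additive Gaussian noise sd.
#' @param seed Integer seed.
#' @return Numeric score per participant.
#' @export
simulate_behavior <- function(features, effects, noise_sd = 1, seed = 1L) {
  set.seed(seed)
  score <- as.numeric(features[, effects$edge, drop = FALSE] %*% effects$beta)
  score + rnorm(nrow(features), sd = noise_sd)
}

#' Cohort specification
#'
#' Defaults describe the validation conditions used throughout the package:
#' 20 participants, 1,500 grayordinates (40/40/20 left cortex / right cortex /
#' subcortex), K = 8 planted networks, 3 mm topographic jitter, three
#' three-network hub zones of 25 mm radius, SNR 4, 10 minutes of data at
#' TR 0.8 s (750 frames), 2% motion-spike probability, and behavioral scores
#' driven by three network-pair edges.
#'
#' @param n_participants,n_gray,fractions,K,jitter_sigma_mm,snr,tr_seconds,n_frames
#'   Study-condition parameters (see Details).
#' @param hub_spec List with `n_hubs`, `radius_mm`, `networks_per_hub`.
#' @param motion List with `spike_prob`, `amplitude`.
#' @param behavior List with `effects` (tibble `edge`, `beta`) and `noise_sd`.
#' @param master_seed Integer master seed; all randomness derives from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_participants = 20L, n_gray = 1500L,
                        fractions = c(0.4, 0.4, 0.2), K = 8L,
                        jitter_sigma_mm = 3,
                        hub_spec = list(n_hubs = 3L, radius_mm = 25,
                                        networks_per_hub = 3L),
                        snr = 4, tr_seconds = 0.8, n_frames = 750L,
                        motion = list(spike_prob = 0.02, amplitude = 0.5),
                        behavior = list(effects = tibble(edge = 1:3,
                                                         beta = c(0.8, -0.5, 0.6)),
                                        noise_sd = 0.5),
                        master_seed = 1L) {
  if (K > 14L) abort("K cannot exceed the 14-network palette.")
  structure(list(n_participants = as.integer(n_participants),
                 n_gray = as.integer(n_gray), fractions = fractions,
                 K = as.integer(K), jitter_sigma_mm = jitter_sigma_mm,
                 hub_spec = hub_spec, snr = snr, tr_seconds = tr_seconds,
                 n_frames = as.integer(n_frames), motion = motion,
                 behavior = behavior, master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

#' Cohort preset for overlap / integration-zone validation
#'
#' Overlapping-network recovery imposes a geometric calibration that the
#' template-matching conditions do not: the eta-squared crosstalk that hub
#' zones induce in the profiles of their partner networks scales with the hub
#' share of a network's territory, while genuine hub-membership similarity
#' scales with the territory itself. Hub zones must therefore be small
#' relative to a network (here ~7%) yet still hold at least 30 grayordinates
#' (the minimum cluster size for a detectable zone), which requires a denser
#' space: 4,000 grayordinates with 15 mm hub zones. All other conditions
#' match [cohort_spec()].
#'
#' @param ... Overrides passed to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
omni_cohort_spec <- function(...) {
  args <- list(...)
  defaults <- list(n_gray = 4000L,
                   hub_spec = list(n_hubs = 3L, radius_mm = 15,
                                   networks_per_hub = 3L))
  do.call(cohort_spec, utils::modifyList(defaults, args))
}

#' Generate a synthetic cohort with ground truth
#'
#' Deterministic given the spec's `master_seed`: the space and group
#' partition are built once; per-participant seeds are derived from the
#' master seed for jitter, BOLD, and motion; behavioral scores are generated
#' from the participants' true network-level connectivity.
#'
#' @param spec A [cohort_spec()].
#' @return A `synthetic_cohort`: `space`, `palette`, `truth` (group `labels`,
#'   `centers`, `hubs`), `participants` (list with `ts`, `motion`,
#'   `truth` = per-participant planting), `behavior` (`scores`, `effects`,
#'   `features`), and the `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  space <- make_space(spec$n_gray, spec$fractions, seed = spec$master_seed)
  palette <- canonical_networks()[seq_len(spec$K)]
  centers <- group_centers(space, spec$K)
  hubs <- place_hubs(space, centers, n_hubs = spec$hub_spec$n_hubs,
                     radius_mm = spec$hub_spec$radius_mm,
                     networks_per_hub = spec$hub_spec$networks_per_hub)
  group_truth <- plant_networks(space, spec$K, jitter_sigma_mm = 0,
                                hubs = hubs, participant_seed = spec$master_seed,
                                centers = centers, palette = palette)
  set.seed(spec$master_seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                             spec$n_participants * 3L),
                  ncol = 3L)
  participants <- vector("list", spec$n_participants)
  for (p in seq_len(spec$n_participants)) {
    planted <- plant_networks(space, spec$K,
                              jitter_sigma_mm = spec$jitter_sigma_mm,
                              hubs = hubs, participant_seed = seeds[p, 1L],
                              centers = centers, palette = palette)
    ts <- simulate_bold(planted$W, space, spec$n_frames,
                        tr_seconds = spec$tr_seconds, snr = spec$snr,
                        seed = seeds[p, 2L])
    motion <- simulate_motion(spec$n_frames,
                              spike_prob = spec$motion$spike_prob,
                              amplitude = spec$motion$amplitude,
                              seed = seeds[p, 3L])
    participants[[p]] <- list(id = p, ts = ts, motion = motion,
                              truth = planted)
  }
  # network-level true connectivity features for behavior
  features <- t(vapply(participants, function(pt) {
    nm <- network_mean_timeseries(pt$ts, pt$truth$labels)
    cc <- cor(nm)
    cc[upper.tri(cc)]
  }, numeric(spec$K * (spec$K - 1L) / 2L)))
  scores <- simulate_behavior(features, spec$behavior$effects,
                              noise_sd = spec$behavior$noise_sd,
                              seed = spec$master_seed + 7L)
  structure(list(space = space, palette = palette,
                 truth = list(labels = group_truth$labels, centers = centers,
                              hubs = hubs, group_overlap = group_truth$overlap),
                 participants = participants,
                 behavior = list(scores = scores,
                                 effects = spec$behavior$effects,
                                 features = features),
                 spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", length(x$participants), " participants, ",
      x$space$n_gray, " grayordinates, K = ", x$spec$K, ", SNR = ",
      x$spec$snr, ", jitter = ", x$spec$jitter_sigma_mm, " mm\n", sep = "")
  invisible(x)
}
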