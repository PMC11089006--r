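# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# Small cohort for module-level recovery tests: 6 participants, 300
# grayordinates, 5 networks, 150 frames. Fast to simulate; planted structure
# is still recoverable at SNR 4.
small_cohort <- function() {
  if (is.null(.fixtures$small)) {
    .fixtures$small <- generate_cohort(cohort_spec(
      n_participants = 6L, n_gray = 300L, K = 5L, n_frames = 150L,
      hub_spec = list(n_hubs = 2L, radius_mm = 10, networks_per_hub = 3L),
      master_seed = 11L))
  }
  .fixtures$small
}

small_templates <- function() {
  if (is.null(.fixtures$small_tmpl)) {
    co <- small_cohort()
    sm <- lapply(1:3, function(p)
      participant_seed_maps(co$participants[[p]]$ts, co$truth$labels))
    .fixtures$small_tmpl <- build_templates(sm, palette = co$palette)
  }
  .fixtures$small_tmpl
}

# scalar-loop eta-squared oracle, independent of the package implementation
eta_oracle <- function(a, b) {
  num <- 0; m <- numeric(length(a))
  for (i in seq_along(a)) {
    m[i] <- (a[i] + b[i]) / 2
    num <- num + (a[i] - m[i])^2 + (b[i] - m[i])^2
  }
  Mbar <- mean(m)
  den <- 0
  for (i in seq_along(a)) den <- den + (a[i] - Mbar)^2 + (b[i] - Mbar)^2
  1 - num / den
}

# brute-force two-pass Pearson oracle
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# toy space on a line: n points 1 mm apart, cortical unless stated
line_space <- function(n, structure = rep("LEFT_CORTEX", n)) {
  adj <- if (n > 1L) cbind(seq_len(n - 1L), 2:n) else matrix(integer(0), ncol = 2)
  gray_space(cbind(seq_len(n), 0, 0), structure, adjacency = adj)
}
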