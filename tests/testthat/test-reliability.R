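test_that("NMI is 1 for identical or relabeled maps and symmetric", {
  sp <- line_space(60)
  set.seed(1)
  lab <- sample(1:4, 60, replace = TRUE)
  pal <- canonical_networks()[1:4]
  A <- label_map(lab, sp, pal)
  expect_equal(nmi(A, A), 1)
  # permuting labels leaves NMI at 1
  perm <- c(3L, 4L, 1L, 2L)
  B <- label_map(perm[lab], sp, pal)
  expect_equal(nmi(A, B), 1)
  # symmetry
  set.seed(2)
  C <- label_map(sample(0:4, 60, replace = TRUE), sp, pal)
  expect_equal(nmi(A, C), nmi(C, A))
})

test_that("NMI of independent maps is near zero; edge contracts hold", {
  set.seed(3)
  a <- sample(1:4, 10000, replace = TRUE)
  b <- sample(1:4, 10000, replace = TRUE)
  expect_lt(nmi(a, b), 0.02)
  # zero-entropy side with differing partition -> 0
  expect_equal(nmi(rep(1L, 100), rep(c(1L, 2L), 50)), 0)
  # both constant and identical -> 1
  expect_equal(nmi(rep(1L, 100), rep(1L, 100)), 1)
  # unassigned grayordinates are excluded pairwise
  a2 <- c(0L, 1L, 1L, 2L, 2L)
  b2 <- c(1L, 1L, 1L, 2L, 0L)
  expect_equal(nmi(a2, b2), nmi(a2[c(2, 3, 4)], b2[c(2, 3, 4)]))
  expect_error(nmi(c(0L, 0L), c(1L, 0L)), "assigned")
})

test_that("split-half masks partition the frames", {
  m <- split_half_masks(10, "interleaved")
  expect_equal(m[[1]]$retained, rep(c(TRUE, FALSE), 5))
  expect_identical(m[[1]]$retained, !m[[2]]$retained)
  m2 <- split_half_masks(11, "contiguous")
  expect_equal(m2[[1]]$retained_count, 5)
  expect_identical(m2[[1]]$retained, !m2[[2]]$retained)
})

test_that("split-half reliability separates intra from null on synthetic data", {
  co <- small_cohort()
  tmpl <- small_templates()
  res <- split_half(lapply(co$participants, `[[`, "ts"),
                    function(ts, mask) template_match(ts, tmpl, mask),
                    seed = 4)
  expect_gt(mean(res$intra$nmi), mean(res$null$nmi))
  expect_lt(res$p_value, 0.01)
  expect_identical(res$variance_assumption, "unequal")
  # Welch dof is fractional in general
  expect_true(is.numeric(res$dof))
  g <- glance(res)
  expect_equal(g$n_participants, 6)
  # same seed reproduces the result object
  res2 <- split_half(lapply(co$participants, `[[`, "ts"),
                     function(ts, mask) template_match(ts, tmpl, mask),
                     seed = 4)
  expect_identical(res$intra, res2$intra)
  expect_equal(res$t_statistic, res2$t_statistic)
})

test_that("identical halves give intra NMI of exactly 1", {
  co <- small_cohort()
  tmpl <- small_templates()
  # map_fun ignoring the mask: both halves map the full series
  res <- split_half(lapply(co$participants[1:3], `[[`, "ts"),
                    function(ts, mask) template_match(ts, tmpl),
                    seed = 1)
  expect_equal(res$intra$nmi, rep(1, 3))
})

test_that("brain-behavior vectors match the per-edge scalar oracle", {
  set.seed(5)
  n <- 30
  conns <- lapply(1:n, function(i) {
    m <- cor(matrix(rnorm(60), 12, 5)); m
  })
  beh <- rnorm(n)
  bb <- brain_behavior_vector(conns, beh)
  ut <- which(upper.tri(conns[[1]]))
  for (e in c(1, 4, 9)) {
    edge_vals <- vapply(conns, function(m) m[ut[e]], numeric(1))
    expect_equal(bb[e], pearson_oracle(edge_vals, beh), tolerance = 1e-12)
  }
  # behavior equal to an edge's strengths correlates 1 at that edge
  beh2 <- vapply(conns, function(m) m[ut[3]], numeric(1))
  expect_equal(brain_behavior_vector(conns, beh2)[3], 1)
  # independent noise: small, roughly symmetric correlations
  set.seed(6)
  conns2 <- lapply(1:100, function(i) cor(matrix(rnorm(200), 20, 10)))
  bb2 <- brain_behavior_vector(conns2, rnorm(100))
  expect_lt(max(abs(bb2)), 0.5)
  expect_lt(abs(mean(bb2 > 0) - 0.5), 0.15)
  expect_error(brain_behavior_vector(conns[1:3], beh[1:3]), "at least 4")
  expect_error(brain_behavior_vector(conns, rep(1, n)), "zero variance")
})

test_that("rise-to-maximum fit recovers noiseless parameters exactly", {
  x <- c(25, 50, 100, 200, 400, 800, 1600, 3200)
  y <- 0.3 + 0.6 * (1 - exp(-0.004 * x))
  fit <- fit_rise_to_max(x, y)
  expect_equal(fit$y0, 0.3, tolerance = 1e-6)
  expect_equal(fit$a, 0.6, tolerance = 1e-6)
  expect_equal(fit$b, 0.004, tolerance = 1e-6)
  expect_gt(fit$r_squared, 1 - 1e-10)
  # constant y flags degenerate with a = 0
  fitc <- fit_rise_to_max(x, rep(0.5, 8))
  expect_true(fitc$degenerate)
  expect_equal(fitc$a, 0)
  # tidy/glance methods
  expect_equal(tidy(fit)$estimate[1], fit$y0)
  expect_equal(glance(fit)$b, fit$b)
})

test_that("rise-to-maximum fit recovers b within 20% under noise", {
  set.seed(7)
  sizes <- c(25, 50, 100, 200, 400, 800, 1600, 3200)
  errs <- replicate(10, {
    x <- rep(sizes, each = 10)
    y <- 0.3 + 0.6 * (1 - exp(-0.004 * x)) + rnorm(length(x), sd = 0.02)
    fit <- fit_rise_to_max(x, y)
    abs(fit$b - 0.004) / 0.004
  })
  expect_lt(mean(errs), 0.2)
})

test_that("subset reliability rises with sample size and is reproducible", {
  co <- small_cohort()
  # per-participant network-level connectivity + planted behavior
  conns <- lapply(co$participants, function(pt) {
    nm <- network_mean_timeseries(pt$ts, pt$truth$labels)
    cor(nm)
  })
  beh <- co$behavior$scores
  reference <- co$behavior$effects  # build a reference from the truth features
  ref_vec <- brain_behavior_vector(conns, beh)
  curve <- subset_reliability(conns, beh, ref_vec, sizes = c(4, 5, 6),
                              reps = 8, seed = 9)
  expect_equal(nrow(curve$means), 3)
  # full-sample subset equals the reference exactly
  full <- curve$samples[curve$samples$size == 6, ]
  expect_true(all(abs(full$correlation - 1) < 1e-12))
  # non-decreasing means within Monte-Carlo error
  expect_gt(curve$means$mean_correlation[3],
            curve$means$mean_correlation[1] - 0.05)
  curve2 <- subset_reliability(conns, beh, ref_vec, sizes = c(4, 5, 6),
                               reps = 8, seed = 9)
  expect_identical(curve$samples, curve2$samples)
  expect_error(subset_reliability(conns, beh, ref_vec, sizes = 3, seed = 1),
               "at least 4")
})

test_that("subset reliability accepts any parcellation's connectivity", {
  # pure-harness property: works with parcel matrices of any size
  set.seed(10)
  conns <- lapply(1:12, function(i) cor(matrix(rnorm(300), 30, 10)))
  beh <- rnorm(12)
  ref <- brain_behavior_vector(conns, beh)
  curve <- subset_reliability(conns, beh, ref, sizes = c(4, 6, 8), reps = 3,
                              seed = 2)
  expect_equal(nrow(curve$samples), 9)
})
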