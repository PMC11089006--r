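test_that("probability maps are assignment frequencies", {
  sp <- line_space(4)
  pal <- c("DMN", "Vis")
  m1 <- label_map(c(1L, 1L, 2L, 0L), sp, pal)
  m2 <- label_map(c(2L, 1L, 2L, 0L), sp, pal)
  atlas <- probability_maps(list(m1, m2))
  expect_equal(atlas$probs["DMN", ], c(0.5, 1, 0, 0))
  expect_equal(atlas$probs["Vis", ], c(0.5, 0, 1, 0))
  expect_identical(atlas$source_mode, "single_assignment")
  # identical cohorts give probabilities in {0, 1}
  atlas2 <- probability_maps(list(m1, m1, m1))
  expect_true(all(atlas2$probs %in% c(0, 1)))
  # column sums bounded by 1 in single-assignment mode
  expect_true(all(colSums(atlas$probs) <= 1 + 1e-12))
  # self-concatenation invariance
  atlas3 <- probability_maps(list(m1, m2, m1, m2))
  expect_equal(atlas3$probs, atlas$probs)
})

test_that("tidiers and plot builders return well-formed objects", {
  sp <- line_space(4)
  pal <- c("DMN", "Vis")
  m1 <- label_map(c(1L, 1L, 2L, 0L), sp, pal)
  atlas <- probability_maps(list(m1, label_map(c(2L, 1L, 2L, 0L), sp, pal)))
  td <- tidy(atlas)
  expect_named(td, c("grayordinate", "network", "probability"))
  expect_true(all(td$probability > 0 & td$probability <= 1))
  expect_s3_class(autoplot(m1), "ggplot")
  expect_s3_class(autoplot(scalar_map(1:4, sp)), "ggplot")
  expect_named(tidy(m1), c("grayordinate", "structure", "label", "network"))
})

test_that("probability maps accept overlapping cohorts", {
  sp <- line_space(3)
  pal <- c("A", "B")
  om1 <- overlap_map(matrix(c(1, 1, 0, 0, 1, 1), 2, byrow = TRUE), sp, pal)
  om2 <- overlap_map(matrix(c(1, 0, 0, 0, 1, 0), 2, byrow = TRUE), sp, pal)
  atlas <- probability_maps(list(om1, om2))
  expect_identical(atlas$source_mode, "omni")
  expect_equal(atlas$probs["A", ], c(1, 0.5, 0))
  expect_equal(atlas$probs["B", ], c(0, 1, 0.5))
})

test_that("ROI derivation applies the threshold and 30-grayordinate rule exactly", {
  sp <- line_space(100)
  pal <- c("DMN", "Vis")
  probs <- matrix(0, 2, 100, dimnames = list(pal, NULL))
  probs[1, 11:50] <- 0.9    # 40-grayordinate plateau -> kept
  probs[2, 60:88] <- 0.9    # 29-grayordinate plateau -> dropped
  atlas <- structure(list(probs = probs, palette = pal, n_participants = 10,
                          source_mode = "single_assignment", space = sp),
                     class = "probability_atlas")
  parc <- derive_roiset(atlas, p_threshold = 0.8)
  expect_equal(nrow(parc$parcels), 1)
  expect_equal(parc$parcels$network, "DMN")
  expect_equal(parc$parcels$size, 40)
  expect_identical(parc$members[[1]], 11:50)
  # monotone in threshold: raising it never grows a parcel
  expect_warning(parc2 <- derive_roiset(atlas, p_threshold = 0.95),
                 "Empty parcellation")
  expect_equal(length(parc2$members), 0)
})

test_that("single-assignment parcels are disjoint at thresholds above 0.5", {
  sp <- line_space(200)
  pal <- c("DMN", "Vis")
  set.seed(1)
  cohort <- lapply(1:10, function(i)
    label_map(c(rep(1L, 100), rep(2L, 100)), sp, pal))
  # add disagreement on the boundary
  cohort[[1]]$labels[95:105] <- 2L
  cohort[[2]]$labels[95:105] <- 1L
  atlas <- probability_maps(cohort)
  parc <- derive_roiset(atlas, p_threshold = 0.75)
  all_members <- unlist(parc$members)
  expect_equal(anyDuplicated(all_members), 0)
})

test_that("integration zones threshold the cohort mean overlap count", {
  sp <- line_space(100)
  pal <- c("A", "B", "C")
  mk <- function(cols3) {
    m <- matrix(0L, 3, 100)
    m[, cols3] <- 1L          # three networks converge on cols3
    m[1, setdiff(1:100, cols3)] <- 1L
    overlap_map(m, sp, pal)
  }
  cohort <- lapply(1:5, function(i) mk(30:70))
  iz <- integration_zones(cohort, threshold = 2.2)
  expect_equal(iz$mean_count$values[50], 3)
  expect_equal(iz$mean_count$values[10], 1)
  expect_equal(length(iz$zones$members), 1)
  expect_identical(iz$zones$members[[1]], 30:70)
  # identical cohort: mean equals any member's counts
  expect_equal(iz$mean_count$values, colSums(cohort[[1]]$membership))
  # threshold above the maximum -> empty set
  iz2 <- integration_zones(cohort, threshold = 4)
  expect_equal(length(iz2$zones$members), 0)
})

test_that("parcel time series are group-by means", {
  sp <- line_space(10)
  set.seed(2)
  v <- matrix(rnorm(80), 8, 10)
  ts <- dense_timeseries(v, sp, 1)
  parc <- structure(list(
    parcels = tibble::tibble(parcel_id = 1:2, network = c("A", "B"),
                             size = c(4L, 1L)),
    members = list(1:4, 7L), threshold = 0.8, space = sp),
    class = "parcellation")
  pts <- parcellate_timeseries(ts, parc)
  expect_equal(pts[, 1], rowMeans(v[, 1:4]))
  expect_equal(pts[, 2], v[, 7])  # singleton parcel
  # constant parcel gives a constant series
  v2 <- v; v2[, 1:4] <- 3
  expect_equal(unname(parcellate_timeseries(dense_timeseries(v2, sp, 1),
                                            parc)[, 1]), rep(3, 8))
})

test_that("network block statistics match brute-force enumeration", {
  set.seed(3)
  n <- 6
  pc <- cor(matrix(rnorm(50 * n), 50, n))
  nets <- c("A", "A", "A", "B", "B", "C")
  st <- network_block_stats(pc, nets)
  within_a <- st$mean_r[st$network_a == "A" & st$kind == "within"]
  expect_equal(within_a, mean(c(pc[1, 2], pc[1, 3], pc[2, 3])))
  between_ab <- st$mean_r[st$network_a == "A" & st$network_b == "B"]
  expect_equal(between_ab, mean(pc[1:3, 4:5]))
  # single-parcel network has undefined within-network connectivity
  within_c <- st[st$network_a == "C" & st$kind == "within", ]
  expect_true(is.na(within_c$mean_r))
  # two perfectly coupled parcels give within = 1
  pc2 <- matrix(1, 2, 2)
  st2 <- network_block_stats(pc2, c("A", "A"))
  expect_equal(st2$mean_r[st2$kind == "within"], 1)
})

test_that("independent parcels show near-zero within-network connectivity", {
  set.seed(4)
  v <- matrix(rnorm(2000 * 4), 2000, 4)
  pc <- cor(v)
  st <- network_block_stats(pc, rep("A", 4))
  expect_lt(abs(st$mean_r[st$kind == "within"]), 0.1)
})
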