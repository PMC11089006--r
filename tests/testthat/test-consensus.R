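test_that("community detection separates disconnected cliques deterministically", {
  # two 4-cliques
  clique <- function(nodes) {
    p <- t(combn(nodes, 2))
    tibble::tibble(i = p[, 1], j = p[, 2], w = 1)
  }
  edges <- dplyr::bind_rows(clique(1:4), clique(5:8))
  sol <- detect_communities(edges, 8)
  expect_length(unique(sol$membership), 2)
  expect_true(all(sol$membership[1:4] == sol$membership[1]))
  expect_true(all(sol$membership[5:8] == sol$membership[5]))
  # determinism
  sol2 <- detect_communities(edges, 8)
  expect_identical(sol$membership, sol2$membership)
  # isolated node gets community 0
  sol3 <- detect_communities(edges, 9)
  expect_equal(sol3$membership[9], 0L)
  expect_error(detect_communities(edges[0, ], 8), "empty")
})

test_that("reference backend recovers a planted partition", {
  set.seed(5)
  n <- 100
  block <- rep(1:2, each = 50)
  rows <- list()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    p <- if (block[i] == block[j]) 0.9 else 0.01
    if (runif(1) < p) rows[[length(rows) + 1L]] <- tibble::tibble(i = i, j = j, w = 1)
  }
  edges <- dplyr::bind_rows(rows)
  sol <- detect_communities(edges, n)
  expect_gt(nmi(sol$membership, block), 0.95)
})

test_that("custom and igraph backends plug into the contract", {
  edges <- tibble::tibble(i = c(1, 2, 3, 4), j = c(2, 3, 1, 5), w = 1)
  custom <- function(e, n) rep(1L, n)
  sol <- detect_communities(edges, 5, backend = custom)
  expect_equal(sol$backend, "custom")
  expect_true(all(sol$membership == 1L))
  sol2 <- detect_communities(edges, 5, backend = "infomap", seed = 3)
  expect_length(sol2$membership, 5)
  expect_true(all(sol2$membership >= 1))
})

test_that("jaccard index matches enumeration", {
  expect_equal(jaccard_index(1:5, 1:5), 1)
  expect_equal(jaccard_index(1:3, 4:6), 0)
  expect_equal(jaccard_index(c(1, 2), c(2, 3)), 1 / 3)
  expect_equal(jaccard_index(integer(0), integer(0)), 0)
})

test_that("communities are relabeled by best Jaccard with the 0.1 floor", {
  sp <- line_space(100)
  pal <- c("DMN", "Vis", "FPN")
  ref <- label_map(c(rep(1L, 40), rep(2L, 40), rep(3L, 20)), sp, pal)
  cfg <- consensus_config(network_priority = pal)
  # community 1 = exact DMN mask; community 2 = tiny sliver with best
  # Jaccard 1/20 = 0.05 < 0.1 -> stays unassigned
  memb <- integer(100)
  memb[1:40] <- 1L
  memb[95] <- 2L
  sol <- structure(list(membership = memb, backend = "test"),
                   class = "community_solution")
  lab <- match_communities(sol, ref, cfg)
  expect_true(all(lab$labels[1:40] == 1L))
  expect_equal(lab$labels[95], 0L)
})

test_that("relabeling floor and greedy claiming follow the stated rules", {
  sp <- line_space(100)
  pal <- c("DMN", "Vis")
  ref <- label_map(c(rep(1L, 50), rep(2L, 50)), sp, pal)
  cfg <- consensus_config(network_priority = pal)
  # community A covers 40 of DMN, community B covers 20 of DMN and 10 of Vis
  memb <- integer(100)
  memb[1:40] <- 1L
  memb[41:60] <- 2L  # 41-50 (DMN) + 51-60 (Vis)
  sol <- structure(list(membership = memb, backend = "test"),
                   class = "community_solution")
  lab <- match_communities(sol, ref, cfg)
  # A wins DMN (Jaccard 40/50 vs 10/60); B falls through to Vis (10/90 >= 0.1)
  expect_true(all(lab$labels[1:40] == 1L))
  expect_true(all(lab$labels[41:60] == 2L))
  # a community below the floor everywhere stays unassigned
  memb2 <- integer(100)
  memb2[1:2] <- 1L
  sol2 <- structure(list(membership = memb2, backend = "test"),
                    class = "community_solution")
  expect_true(all(match_communities(sol2, ref, cfg)$labels == 0L))
})

test_that("consensus takes the sparsest successful assignment", {
  sp <- line_space(3)
  pal <- c("DMN", "Vis")
  mk <- function(v) label_map(v, sp, pal)
  maps <- list(mk(c(0L, 0L, 1L)),   # density 0.3
               mk(c(1L, 0L, 2L)),   # density 0.4
               mk(c(2L, 0L, 2L)))   # density 3
  cons <- consensus_across_densities(maps, c(0.3, 0.4, 3))
  expect_identical(cons$labels, c(1L, 0L, 1L))  # DMN at 0.4; never; DMN at 0.3
  # order of the input list is irrelevant once densities are attached
  cons2 <- consensus_across_densities(maps[c(3, 1, 2)], c(3, 0.3, 0.4))
  expect_identical(cons2$labels, cons$labels)
  # assigned only at the densest threshold
  maps3 <- list(mk(c(0L, 0L, 0L)), mk(c(0L, 2L, 0L)))
  expect_identical(consensus_across_densities(maps3, c(1, 3))$labels,
                   c(0L, 2L, 0L))
})

test_that("small clusters merge into the largest labeled neighbour", {
  sp <- line_space(100)
  pal <- c("DMN", "Vis", "FPN")
  # a 10-grayordinate island of FPN inside Vis territory
  lab <- c(rep(1L, 30), rep(2L, 30), rep(3L, 10), rep(2L, 30))
  lm <- label_map(lab, sp, pal)
  out <- clean_small_clusters(lm, min_cluster = 30)
  expect_true(all(out$labels[61:70] == 2L))
  # identity when nothing is small
  lm2 <- label_map(c(rep(1L, 50), rep(2L, 50)), sp, pal)
  expect_identical(clean_small_clusters(lm2, 30)$labels, lm2$labels)
  # two candidate neighbours: the larger network wins
  lab3 <- c(rep(1L, 45), rep(3L, 10), rep(2L, 45))
  out3 <- clean_small_clusters(label_map(lab3, sp, pal), 30)
  expect_true(all(out3$labels[46:55] %in% c(1L, 2L)))
  # both DMN and Vis have 45; tie resolved deterministically, island gone
  expect_true(all(out3$labels != 3L))
  # no mergeable component below the minimum remains
  for (k in unique(out3$labels[out3$labels > 0])) {
    comps <- space_components(sp, which(out3$labels == k))
    expect_true(all(lengths(comps) >= 30))
  }
})

test_that("cleanup leaves unlabeled-neighbour islands and counts them", {
  sp <- line_space(50)
  pal <- c("DMN", "Vis")
  lab <- c(rep(0L, 20), rep(1L, 10), rep(0L, 20))
  out <- clean_small_clusters(label_map(lab, sp, pal), 30)
  expect_identical(out$labels, lab)
  expect_equal(attr(out, "n_unmergeable"), 1)
})

test_that("small group-level networks are dropped to unassigned", {
  sp <- line_space(1000)
  pal <- c("DMN", "Vis")
  lab <- c(rep(1L, 650), rep(2L, 350))
  out <- drop_small_networks(label_map(lab, sp, pal), min_network_group = 400)
  expect_true(all(out$labels[651:1000] == 0L))
  expect_true(all(out$labels[1:650] == 1L))
})

test_that("multi-density consensus pipeline recovers planted partitions", {
  co <- small_cohort()
  pt <- co$participants[[1]]
  C <- dense_correlation(pt$ts)
  cfg <- consensus_config(densities = c(0.5, 1, 2, 3, 5),
                          network_priority = co$palette,
                          min_cluster = 5L)
  lab <- infomap_consensus(C, co$truth$labels, cfg,
                           exclusion_radius_mm = 20)
  assigned <- lab$labels > 0
  expect_gt(mean(assigned), 0.5)
  agree <- mean(lab$labels[assigned] == pt$truth$labels$labels[assigned])
  expect_gt(agree, 0.8)
})
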