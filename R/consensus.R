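#' Community detection on a thresholded edge list
#'
#' Pluggable backend contract: any function mapping an edge list (tibble with
#' `i`, `j`, `w`) and node count to an integer membership vector. Two backends
#' ship with the package:
#' \describe{
#'   \item{`"reference"`}{Deterministic: connected components of the
#'     thresholded graph followed by a weighted asynchronous label-propagation
#'     refinement in fixed vertex order (ties to the smallest label).}
#'   \item{`"infomap"`}{The map-equation optimizer via
#'     [igraph::cluster_infomap()], seeded for reproducibility.}
#' }
#'
#' @param edges Tibble/data frame with columns `i`, `j`, `w` (undirected).
#' @param n_nodes Number of nodes (isolated nodes receive community 0).
#' @param backend `"reference"`, `"infomap"`, or a function
#'   `(edges, n_nodes) -> integer membership`.
#' @param seed Integer seed for stochastic backends (default 1).
#' @return A `community_solution`: integer `membership` of length `n_nodes`
#'   (0 = not in any community, i.e. isolated), plus `backend` name.
#' @export
detect_communities <- function(edges, n_nodes, backend = "reference", seed = 1L) {
  if (nrow(edges) == 0L) abort("Edge list is empty.")
  if (is.function(backend)) {
    memb <- tryCatch(backend(edges, n_nodes),
                     error = function(e) abort(paste0(
                       "Custom community backend failed: ", conditionMessage(e))))
    nm <- "custom"
  } else if (backend == "reference") {
    memb <- reference_backend(edges, n_nodes, seed = seed)
    nm <- "reference"
  } else if (backend == "infomap") {
    g <- igraph::graph_from_data_frame(
      data.frame(from = edges$i, to = edges$j),
      directed = FALSE,
      vertices = data.frame(name = seq_len(n_nodes)))
    w <- pmax(edges$w, .Machine$double.eps)  # infomap needs positive weights
    set.seed(seed)
    cl <- tryCatch(igraph::cluster_infomap(g, e.weights = w),
                   error = function(e) abort(paste0(
                     "Backend 'infomap' failed: ", conditionMessage(e))))
    memb <- as.integer(igraph::membership(cl))
    nm <- "infomap"
  } else {
    abort("Unknown backend; use 'reference', 'infomap', or a function.")
  }
  memb <- canonicalize_membership(memb, edges, n_nodes)
  structure(list(membership = memb, backend = nm), class = "community_solution")
}

# isolated nodes -> 0; community ids renumbered 1..n by first appearance
canonicalize_membership <- function(memb, edges, n_nodes) {
  memb <- as.integer(memb)
  deg <- tabulate(c(edges$i, edges$j), nbins = n_nodes)
  memb[deg == 0L] <- 0L
  pos <- memb > 0L
  memb[pos] <- match(memb[pos], unique(memb[pos]))
  memb
}

# connected components, then weighted label propagation within each
# component under a fixed seed (reproducible given the seed)
reference_backend <- function(edges, n_nodes, seed = 1L) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$i, to = edges$j),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n_nodes)))
  w <- pmax(edges$w - min(edges$w, 0), .Machine$double.eps)
  comp <- igraph::components(g)$membership
  set.seed(seed)
  lp <- igraph::cluster_label_prop(g, weights = w)
  lab <- as.integer(igraph::membership(lp))
  # label propagation never merges across components; combine the two ids so
  # distinct components stay distinct even if propagation returns one label
  as.integer(interaction(comp, lab, drop = TRUE))
}

#' Jaccard similarity of two index sets
#'
#' @param A,B Integer vectors (treated as sets).
#' @return |A intersect B| / |A union B|; 0 when both are empty.
#' @export
jaccard_index <- function(A, B) {
  A <- unique(A); B <- unique(B)
  u <- length(union(A, B))
  if (u == 0L) return(0)
  length(intersect(A, B)) / u
}

#' Consensus configuration for multi-density community detection
#'
#' @param densities Ascending edge densities in percent (default the eight
#'   densities 0.3-3; use `c(densities, 4, 5)` for combined
#'   cortical+subcortical runs).
#' @param min_jaccard Minimum Jaccard index for a community to receive a
#'   network label (default 0.1).
#' @param network_priority Networks in claiming order, large well-known
#'   networks first (default [network_priority()]).
#' @param min_cluster Minimum contiguous cluster size in grayordinates
#'   (default 30).
#' @param min_network_group Group-level networks at or below this size are
#'   relabeled unassigned (default 400).
#' @return A `consensus_config` list.
#' @export
consensus_config <- function(densities = c(0.3, 0.4, 0.5, 1, 1.5, 2, 2.5, 3),
                             min_jaccard = 0.1,
                             network_priority = NULL,
                             min_cluster = 30L, min_network_group = 400L) {
  if (is.unsorted(densities, strictly = TRUE)) {
    abort("`densities` must be strictly ascending.")
  }
  if (is.null(network_priority)) network_priority <- precisionmap::network_priority()
  structure(list(densities = densities, min_jaccard = min_jaccard,
                 network_priority = network_priority,
                 min_cluster = as.integer(min_cluster),
                 min_network_group = as.integer(min_network_group)),
            class = "consensus_config")
}

#' Relabel detected communities against a reference parcellation
#'
#' Networks are claimed greedily in priority order: each network (large,
#' well-known networks first) is claimed by the still-unlabeled community
#' with the highest Jaccard index to that network's reference mask, provided
#' it reaches `min_jaccard`. Communities left unlabeled after the claiming
#' pass then take their best-matching network regardless of prior claims
#' (several communities may therefore carry one network name); communities
#' whose best Jaccard is below `min_jaccard` stay unassigned.
#'
#' @param sol A `community_solution` from [detect_communities()].
#' @param reference A [label_map()] with the reference networks.
#' @param cfg A [consensus_config()].
#' @return A [label_map()] on the reference palette.
#' @export
match_communities <- function(sol, reference, cfg = consensus_config()) {
  memb <- sol$membership
  comms <- setdiff(unique(memb), 0L)
  ref_sets <- lapply(seq_along(reference$palette),
                     function(k) which(reference$labels == k))
  names(ref_sets) <- reference$palette
  J <- matrix(0, nrow = length(comms), ncol = length(reference$palette),
              dimnames = list(NULL, reference$palette))
  comm_sets <- lapply(comms, function(cid) which(memb == cid))
  for (ci in seq_along(comms)) {
    for (k in seq_along(ref_sets)) {
      J[ci, k] <- jaccard_index(comm_sets[[ci]], ref_sets[[k]])
    }
  }
  assign <- setNames(rep(0L, length(comms)), comms)
  taken <- logical(length(comms))
  for (nw in intersect(cfg$network_priority, reference$palette)) {
    k <- match(nw, reference$palette)
    cand <- which(!taken & J[, k] >= cfg$min_jaccard)
    if (length(cand) == 0L) next
    win <- cand[which.max(J[cand, k])]
    assign[win] <- k
    taken[win] <- TRUE
  }
  # leftovers: best network overall (many-to-one allowed)
  for (ci in which(!taken)) {
    k <- which.max(J[ci, ])
    if (J[ci, k] >= cfg$min_jaccard) assign[ci] <- as.integer(k)
  }
  lab <- rep(0L, length(memb))
  pos <- memb > 0L
  lab[pos] <- assign[match(memb[pos], comms)]
  label_map(lab, reference$space, reference$palette)
}

#' Sparsest-threshold consensus across densities
#'
#' Each grayordinate takes the network label it carried at the sparsest
#' (smallest) density at which it was successfully assigned; grayordinates
#' never assigned stay unassigned.
#'
#' @param labelled_solutions List of [label_map()]s, one per density.
#' @param densities Numeric densities matching the list (any order; the maps
#'   are sorted ascending before the scan).
#' @return A [label_map()].
#' @export
consensus_across_densities <- function(labelled_solutions, densities) {
  if (length(labelled_solutions) == 0L) abort("Need at least one solution.")
  if (length(densities) != length(labelled_solutions)) {
    abort("`densities` must match the number of solutions.")
  }
  ord <- order(densities)
  maps <- labelled_solutions[ord]
  n <- length(maps[[1L]]$labels)
  pal <- maps[[1L]]$palette
  for (m in maps) {
    if (length(m$labels) != n || !identical(m$palette, pal)) {
      abort("All solutions must share a space and palette.")
    }
  }
  lab <- rep(0L, n)
  for (m in maps) {
    open <- lab == 0L
    lab[open] <- m$labels[open]
  }
  label_map(lab, maps[[1L]]$space, pal)
}

#' Merge small contiguous clusters into neighbouring networks
#'
#' Connected components of equal-label grayordinates smaller than
#' `min_cluster` are reassigned to the adjacent network with the largest total
#' size; the process iterates until stable. Components with no labeled
#' neighbour remain and are counted in `attr(, "n_unmergeable")`.
#'
#' @param labels A [label_map()].
#' @param min_cluster Minimum component size (default 30).
#' @return A cleaned [label_map()].
#' @export
clean_small_clusters <- function(labels, min_cluster = 30L) {
  space <- labels$space
  lab <- labels$labels
  nb <- adjacency_list(space)
  repeat {
    changed <- FALSE
    n_unmergeable <- 0L
    net_sizes <- tabulate(lab[lab > 0L], nbins = length(labels$palette))
    for (k in sort(unique(lab[lab > 0L]))) {
      comps <- space_components(space, which(lab == k))
      for (comp in comps) {
        if (length(comp) >= min_cluster) next
        nbr <- setdiff(unique(unlist(nb[comp])), comp)
        nbr_labs <- setdiff(unique(lab[nbr]), c(0L, k))
        if (length(nbr_labs) == 0L) {
          n_unmergeable <- n_unmergeable + 1L
          next
        }
        target <- nbr_labs[which.max(net_sizes[nbr_labs])]
        lab[comp] <- target
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- label_map(lab, space, labels$palette)
  attr(out, "n_unmergeable") <- n_unmergeable
  out
}

#' Drop small group-level networks
#'
#' Networks with `min_network_group` or fewer member grayordinates are
#' relabeled unassigned. Applied to group-average consensus runs only.
#'
#' @param labels A [label_map()].
#' @param min_network_group Size threshold (default 400).
#' @return A [label_map()].
#' @export
drop_small_networks <- function(labels, min_network_group = 400L) {
  lab <- labels$labels
  sizes <- tabulate(lab[lab > 0L], nbins = length(labels$palette))
  drop <- which(sizes > 0L & sizes <= min_network_group)
  lab[lab %in% drop] <- 0L
  label_map(lab, labels$space, labels$palette)
}

#' Multi-density community-detection consensus map for one participant
#'
#' Runs the full pipeline: distance exclusion, density thresholding at each
#' configured density, community detection, Jaccard relabeling to the
#' reference, sparsest-threshold consensus, small-cluster cleanup.
#'
#' @param C A [conn_matrix()] (raw correlations).
#' @param reference Reference [label_map()].
#' @param cfg A [consensus_config()].
#' @param backend Community-detection backend (see [detect_communities()]).
#' @param exclusion_radius_mm Short-distance exclusion radius (default 30).
#' @param seed Seed for stochastic backends.
#' @return A [label_map()].
#' @export
infomap_consensus <- function(C, reference, cfg = consensus_config(),
                              backend = "reference",
                              exclusion_radius_mm = 30, seed = 1L) {
  Cx <- distance_exclude(C, radius_mm = exclusion_radius_mm)
  maps <- lapply(cfg$densities, function(d) {
    edges <- density_threshold(Cx, d)
    sol <- detect_communities(edges, n_nodes = C$space$n_gray,
                              backend = backend, seed = seed)
    match_communities(sol, reference, cfg)
  })
  cons <- consensus_across_densities(maps, cfg$densities)
  clean_small_clusters(cons, min_cluster = cfg$min_cluster)
}
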