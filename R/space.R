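#' Grayordinate space
#'
#' A grayordinate space indexes the sampling units of combined surface +
#' volume brain data: cortical surface vertices of both hemispheres and
#' subcortical voxels. It carries 3D coordinates (mm), a per-grayordinate
#' structure tag and a symmetric neighbour relation used for contiguity
#' operations (connected-component cluster rules).
#'
#' @param coords Numeric matrix, `n_gray` rows by 3 columns (x, y, z in mm).
#' @param structure Character vector of per-grayordinate tags, each one of
#'   `"LEFT_CORTEX"`, `"RIGHT_CORTEX"`, `"SUBCORTEX"`.
#' @param adjacency Optional adjacency: either an integer 2-column matrix of
#'   undirected edges (1-based grayordinate indices) or `NULL`, in which case
#'   a symmetrized k-nearest-neighbour graph (k = 6) on `coords` is built.
#'
#' @return An object of class `gray_space` with fields `n_gray`, `coords`,
#'   `structure` and `adjacency` (2-column edge matrix, i < j).
#' @export
gray_space <- function(coords, structure, adjacency = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  if (ncol(coords) != 3L) abort("`coords` must have 3 columns (x, y, z).")
  if (!all(is.finite(coords))) abort("All coordinates must be finite.")
  n <- nrow(coords)
  structure <- as.character(structure)
  if (length(structure) != n) {
    abort("`structure` length must equal the number of coordinate rows.")
  }
  tags <- c("LEFT_CORTEX", "RIGHT_CORTEX", "SUBCORTEX")
  if (!all(structure %in% tags)) {
    abort(paste0("Structure tags must be one of: ", paste(tags, collapse = ", "), "."))
  }
  if (is.null(adjacency)) {
    adjacency <- knn_edges(coords, k = 6L)
  } else {
    adjacency <- canonical_edges(adjacency, n)
  }
  structure(
    list(n_gray = n, coords = coords, structure = structure,
         adjacency = adjacency),
    class = "gray_space"
  )
}

# symmetrized kNN edge list, canonical i < j, no self loops
knn_edges <- function(coords, k = 6L) {
  n <- nrow(coords)
  k <- min(k, n - 1L)
  if (k < 1L) return(matrix(integer(0), ncol = 2L))
  d2 <- as.matrix(stats::dist(coords))^2
  diag(d2) <- Inf
  nn <- t(apply(d2, 1L, function(row) order(row)[seq_len(k)]))
  edges <- cbind(rep(seq_len(n), each = k), as.integer(t(nn)))
  canonical_edges(edges, n)
}

canonical_edges <- function(edges, n) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) == 0L) return(edges)
  if (any(edges < 1L | edges > n)) abort("Adjacency indices out of range.")
  edges <- edges[edges[, 1L] != edges[, 2L], , drop = FALSE]
  edges <- cbind(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
  edges[!duplicated(edges), , drop = FALSE]
}

#' @export
print.gray_space <- function(x, ...) {
  cat("<gray_space> ", x$n_gray, " grayordinates (",
      sum(x$structure == "LEFT_CORTEX"), " L / ",
      sum(x$structure == "RIGHT_CORTEX"), " R / ",
      sum(x$structure == "SUBCORTEX"), " subcortical), ",
      nrow(x$adjacency), " adjacency edges\n", sep = "")
  invisible(x)
}

#' Neighbour list from a space adjacency
#'
#' @param space A [gray_space()].
#' @return List of integer vectors, one per grayordinate.
#' @keywords internal
adjacency_list <- function(space) {
  nb <- vector("list", space$n_gray)
  e <- space$adjacency
  for (r in seq_len(nrow(e))) {
    i <- e[r, 1L]; j <- e[r, 2L]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  nb
}

#' Connected components of a grayordinate subset
#'
#' Components are computed on the subgraph of the space adjacency induced by
#' `members`, and never span structure boundaries (cortex / subcortex): edges
#' between different structure tags are cut first.
#'
#' @param space A [gray_space()].
#' @param members Integer vector of grayordinate indices (1-based).
#' @param split_structures Cut edges crossing structure tags (default TRUE).
#' @return List of integer vectors, one component each, descending size.
#' @export
space_components <- function(space, members, split_structures = TRUE) {
  members <- sort(unique(as.integer(members)))
  if (length(members) == 0L) return(list())
  e <- space$adjacency
  keep <- e[, 1L] %in% members & e[, 2L] %in% members
  if (split_structures) {
    keep <- keep & space$structure[e[, 1L]] == space$structure[e[, 2L]]
  }
  e <- e[keep, , drop = FALSE]
  g <- igraph::graph_from_edgelist(
    cbind(match(e[, 1L], members), match(e[, 2L], members)),
    directed = FALSE
  )
  g <- igraph::add_vertices(g, max(0L, length(members) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  out <- split(members, comp)
  out[order(-lengths(out))]
}
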