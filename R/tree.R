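#' Neighbor-joining guide tree from a distance matrix
#'
#' Builds the guide tree used for parsimony-based homoplasy inference.
#' Neighbor joining on closed-form (default K2P) distances replaces the
#' maximum-likelihood trees of the full-scale analysis; negative estimated
#' branch lengths are clamped to zero.
#'
#' @param D symmetric distance matrix with genome ids as dimnames, e.g. from
#'   [corrected_distance_matrix()].
#' @return an unrooted `phylo` tree (package \pkg{ape}).
#' @export
build_guide_tree <- function(D) {
  if (nrow(D) < 3L) stop("a guide tree needs at least 3 genomes")
  tr <- ape::nj(stats::as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# postorder edge arrays consumed by the C++ engine
.tree_arrays <- function(tree) {
  tt <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tt$tip.label)
  list(parent = tt$edge[, 1L], child = tt$edge[, 2L],
       ntip = ntip, nnode = ntip + tt$Nnode, tips = tt$tip.label)
}
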