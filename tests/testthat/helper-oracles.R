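# Independent patristic-distance oracle: walk each tip's path to the root
# and sum branch lengths over the symmetric difference of the two paths.
.path_to_root <- function(tree, tip) {
  node <- which(tree$tip.label == tip)
  edges <- integer(0)
  repeat {
    e <- which(tree$edge[, 2] == node)
    if (length(e) == 0) break
    edges <- c(edges, e)
    node <- tree$edge[e, 1]
  }
  edges
}

.oracle_patristic <- function(tree, a, b) {
  pa <- .path_to_root(tree, a)
  pb <- .path_to_root(tree, b)
  shared <- intersect(pa, pb)
  sum(tree$edge.length[setdiff(c(pa, pb), shared)])
}
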