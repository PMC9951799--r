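#' Parse a Newick tree
#'
#' Thin wrapper around [ape::read.tree()] that enforces the properties the
#' meta-analytic model needs: unique leaf names and branch lengths on every
#' edge (zero-length branches are allowed).
#'
#' @param text Newick string, or `NULL` if `path` given.
#' @param path Path to a Newick file.
#' @param strict_lengths Require branch lengths on all edges (default TRUE).
#' @return An [ape::phylo] tree.
#' @export
parse_newick <- function(text = NULL, path = NULL, strict_lengths = TRUE) {
  stopifnot(xor(is.null(text), is.null(path)))
  tree <- tryCatch(
    if (is.null(path)) ape::read.tree(text = text) else ape::read.tree(path),
    error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error: input did not yield a tree")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf names in tree: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  if (strict_lengths && (is.null(tree$edge.length) ||
                         anyNA(tree$edge.length))) {
    stop("tree has missing branch lengths (strict_lengths = TRUE)")
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0, na.rm = TRUE)) {
    stop("negative branch lengths are not allowed")
  }
  tree
}

#' Patristic distance matrix
#'
#' Sum of branch lengths along the unique path between every pair of tips.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @return A symmetric matrix with species names on both dimensions and a
#'   zero diagonal.
#' @export
patristic_matrix <- function(tree) {
  pd <- ape::cophenetic.phylo(tree)
  pd[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Phylogenetic correlation matrix for tree-linked random effects
#'
#' Shared-ancestry correlation between tips: the shared root-to-tip branch
#' length of each pair, scaled to a unit diagonal. For an ultrametric tree
#' this is the shared depth divided by tree height; for a non-ultrametric
#' tree the pairwise shared depth is divided by the geometric mean of the two
#' tip depths (with a warning), which keeps the diagonal at 1 without forcing
#' the tree to be ultrametric. Used as the covariance structure of
#' tree-linked species random effects.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @return Symmetric positive-semidefinite matrix with unit diagonal,
#'   species-labelled.
#' @export
phylo_correlation <- function(tree) {
  V <- ape::vcv(tree)
  depths <- diag(V)
  if (max(depths) - min(depths) > 1e-8 * max(depths)) {
    warning("tree is not ultrametric; correlations scaled by per-tip depths")
  }
  A <- V / sqrt(outer(depths, depths))
  diag(A) <- 1
  A[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Log-scaled phylogenetic distance
#'
#' `log(1 + PD)`. The offset makes the covariate well-defined for
#' conspecific grass-recipient pairs (patristic distance 0), which occur in
#' allelopathy datasets whenever a species is tested against itself.
#'
#' @param pd Patristic distance(s), `>= 0`.
#' @param offset Offset inside the log, default 1.
#' @return `log(offset + pd)` minus `log(offset)` when `offset != 1`, so the
#'   conspecific value is always 0.
#' @export
log_scaled_distance <- function(pd, offset = 1) {
  stopifnot(all(pd >= 0), offset > 0)
  log(offset + pd) - log(offset)
}

# Pairwise log-scaled distance for the grass/recipient pairs of an effect
# table; fatal if any species is absent from the tree.
.pair_log_distance <- function(effects, tree, offset = 1) {
  pd <- patristic_matrix(tree)
  species <- unique(c(effects$grass_species, effects$recipient_species))
  missing <- setdiff(species, rownames(pd))
  if (length(missing) > 0) {
    stop("species absent from tree: ", paste(missing, collapse = ", "))
  }
  raw <- pd[cbind(effects$grass_species, effects$recipient_species)]
  list(pd = raw, logpd = log_scaled_distance(raw, offset = offset))
}
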