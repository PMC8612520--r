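#' Read a Newick phylogeny
#'
#' Parses a rooted Newick tree via \pkg{ape} and validates it for use in
#' the covariance construction: unique tip labels, a branch length on
#' every edge, and no negative lengths.
#'
#' @param path Path to a Newick file.
#' @return An \pkg{ape} `phylo` object.
#' @export
read_newick <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    cg_io_error(sprintf("file not found: %s", path))
  }
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) cg_io_error(
                     sprintf("Newick parse failure in %s: %s",
                             path, conditionMessage(e))))
  if (is.null(tree)) cg_io_error(sprintf("Newick parse failure in %s", path))
  validate_tree(tree)
  tree
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) cg_contract_error("not a phylo object")
  if (anyDuplicated(tree$tip.label)) {
    cg_validation_error("duplicate tip labels in tree")
  }
  if (is.null(tree$edge.length) ||
      length(tree$edge.length) != nrow(tree$edge) ||
      anyNA(tree$edge.length)) {
    bad <- if (is.null(tree$edge.length)) seq_len(nrow(tree$edge)) else
      which(is.na(tree$edge.length))
    lab <- edge_label(tree, bad[1])
    cg_validation_error(sprintf("missing branch length on edge to %s", lab))
  }
  if (any(tree$edge.length < 0)) {
    cg_validation_error(sprintf(
      "negative branch length on edge to %s",
      edge_label(tree, which(tree$edge.length < 0)[1])))
  }
  invisible(tree)
}

edge_label <- function(tree, edge_idx) {
  child <- tree$edge[edge_idx, 2]
  if (child <= length(tree$tip.label)) tree$tip.label[child]
  else sprintf("internal node %d", child)
}

#' Prune a phylogeny to a set of tips
#'
#' Restricts the tree to `keep`, suppressing degree-2 internal nodes by
#' summing branch lengths, so root-to-tip distances of the kept tips are
#' preserved.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to retain (at least 2, all
#'   present in the tree).
#' @return The pruned `phylo` object.
#' @export
prune_tree <- function(tree, keep) {
  validate_tree(tree)
  keep <- unique(as.character(keep))
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing)) {
    cg_validation_error(sprintf("tip label(s) not in tree: %s",
                                paste(missing, collapse = ", ")))
  }
  if (length(keep) < 2L) {
    cg_contract_error("need at least 2 tips to prune to")
  }
  pr <- ape::keep.tip(tree, keep)
  # keep.tip re-roots at the MRCA of the kept set; retain the removed
  # common stem as a root edge so root-to-tip distances are conserved
  old_depth <- ape::node.depth.edgelength(tree)[match(keep[1],
                                                      tree$tip.label)]
  new_depth <- ape::node.depth.edgelength(pr)[match(keep[1], pr$tip.label)]
  stem <- old_depth - new_depth +
    (if (is.null(tree$root.edge)) 0 else tree$root.edge)
  if (stem > 1e-12) pr$root.edge <- stem
  pr
}

#' Brownian-motion variance-covariance matrix of a phylogeny
#'
#' The expected trait covariance under Brownian evolution on the tree:
#' `C[a, b]` is the shared root-to-tip path length of tips `a` and `b`
#' (the depth of their most recent common ancestor), and `C[a, a]` is the
#' root-to-tip distance. With `standardize = TRUE` all entries are divided
#' by the maximum root-to-tip depth, so the diagonal is 1 for every tip of
#' an ultrametric tree and the random-effect scale is comparable across
#' trees.
#'
#' @param tree A `phylo` object with at least 2 tips.
#' @param standardize Divide by the maximum root-to-tip depth?
#'   Default `TRUE`.
#' @return A symmetric positive-semidefinite matrix with tip labels as
#'   dimnames, in the tree's tip order.
#' @export
phylo_covariance <- function(tree, standardize = TRUE) {
  validate_tree(tree)
  if (length(tree$tip.label) < 2L) {
    cg_contract_error("need at least 2 tips for a covariance matrix")
  }
  C <- ape::vcv.phylo(tree)
  if (!is.null(tree$root.edge) && is.finite(tree$root.edge)) {
    C <- C + tree$root.edge # shared stem above the displayed root
  }
  depth <- max(diag(C))
  if (depth <= 0) {
    cg_validation_error("degenerate tree: all root-to-tip distances are 0")
  }
  if (standardize) C <- C / depth
  C
}

# Lower Cholesky factor of C with a small diagonal jitter so that language
# trees containing zero-length branches (identical tips) still factorize.
chol_lower <- function(C, jitter = 1e-8) {
  t(chol(C + diag(jitter, nrow(C))))
}
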