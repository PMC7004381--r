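#' Observed features per sample
#' @param table a feature table.
#' @return named integer vector: per sample, the number of features with
#'   count > 0.
#' @export
observed_features <- function(table) {
  table <- as_feature_table(table)
  colSums(unclass(table) > 0)
}

# Match table rows onto tree tips; errors listing features that are
# observed in the table but missing from the tree.
check_tips <- function(table, tree) {
  present <- rownames(table)[rowSums(table) > 0]
  missing <- setdiff(present, tree$tip.label)
  if (length(missing)) {
    stop("features not found on the tree: ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

# Per-edge descendant sums: a single post-order pass accumulating each
# sample's counts up the tree. Returns edge lengths and an
# n_edge x n_sample matrix of the summed values under each edge's child.
edge_accumulate <- function(values, tree) {
  # values: features x samples, rownames are (a subset of) tip labels
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  nsamp <- ncol(values)
  tr <- stats::reorder(tree, "postorder")
  node_vals <- matrix(0, nrow = ntip + nnode, ncol = nsamp)
  idx <- match(tree$tip.label, rownames(values))
  hit <- !is.na(idx)
  node_vals[which(hit), ] <- values[idx[hit], , drop = FALSE]
  edge <- tr$edge
  for (i in seq_len(nrow(edge))) {
    node_vals[edge[i, 1L], ] <- node_vals[edge[i, 1L], ] + node_vals[edge[i, 2L], ]
  }
  list(lengths = tr$edge.length, props = node_vals[edge[, 2L], , drop = FALSE])
}

#' Faith's phylogenetic diversity
#'
#' Per sample, the total branch length of the union of root-to-tip paths
#' over tips with count > 0 (the path to the root is included).
#'
#' @param table a feature table whose nonzero features are tips of `tree`.
#' @param tree a rooted `phylo` tree with branch lengths.
#' @return named numeric vector of PD values per sample.
#' @export
faith_pd <- function(table, tree) {
  table <- as_feature_table(table)
  check_tips(table, tree)
  acc <- edge_accumulate(unclass(table), tree)
  pd <- colSums(acc$lengths * (acc$props > 0))
  names(pd) <- colnames(table)
  pd
}
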