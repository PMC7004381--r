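# Small programmatic fixtures shared across the test files.

random_table <- function(n_feat = 6, n_samp = 4, max_count = 50, seed = NULL,
                         feature_ids = sprintf("f%02d", seq_len(n_feat))) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rpois(n_feat * n_samp, lambda = max_count / 4), n_feat, n_samp,
              dimnames = list(feature_ids, sprintf("s%02d", seq_len(n_samp))))
  feature_table(m)
}

# four-tip reference tree used by the hand-derived phylogenetic examples
balanced_tree <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

presence_table <- function(sets, features) {
  # sets: named list of character vectors -> 0/1 table
  m <- vapply(sets, function(s) as.integer(features %in% s),
              integer(length(features)))
  rownames(m) <- features
  feature_table(m)
}

simple_taxonomy <- function(feature_ids, lineages) {
  taxonomy_map(feature_ids, lineages)
}

# two-group Dirichlet-multinomial tables from one shared composition,
# optionally with one feature's abundance multiplied in group B
two_group_table <- function(n_feat = 40, n_per_group = 20, depth = 5e4,
                            shift_feature = NULL, shift_fold = 16) {
  g <- rgamma(n_feat, 1)
  comp_a <- g / sum(g)
  comp_b <- comp_a
  if (!is.null(shift_feature)) {
    comp_b[shift_feature] <- comp_b[shift_feature] * shift_fold
    comp_b <- comp_b / sum(comp_b)
  }
  draw <- function(comp, n) {
    vapply(seq_len(n), function(i) as.integer(rmultinom(1, depth, comp)),
           integer(n_feat))
  }
  m <- cbind(draw(comp_a, n_per_group), draw(comp_b, n_per_group))
  dimnames(m) <- list(sprintf("f%03d", seq_len(n_feat)),
                      sprintf("s%03d", seq_len(2 * n_per_group)))
  grouping <- setNames(rep(c("A", "B"), each = n_per_group), colnames(m))
  list(table = feature_table(m), grouping = grouping)
}
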