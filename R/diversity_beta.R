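#' Construct a distance matrix object
#'
#' A square symmetric matrix of non-negative dissimilarities with zero
#' diagonal and sample ids as dimnames.
#'
#' @param values square numeric matrix.
#' @return object of class `distance_matrix`.
#' @export
distance_matrix <- function(values) {
  if (!is.matrix(values) || nrow(values) != ncol(values)) {
    stop("'values' must be a square matrix")
  }
  if (is.null(rownames(values))) stop("distance matrix needs sample ids")
  if (max(abs(values - t(values))) > 1e-12) stop("distance matrix not symmetric")
  if (any(diag(values) != 0)) stop("distance matrix diagonal must be zero")
  if (any(values < 0)) stop("negative dissimilarities")
  values <- (values + t(values)) / 2
  diag(values) <- 0
  class(values) <- c("distance_matrix", class(matrix()))
  values
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("distance_matrix: %d samples\n", nrow(x)))
  print(round(unclass(x)[seq_len(min(6L, nrow(x))),
                         seq_len(min(6L, ncol(x))), drop = FALSE], 4))
  invisible(x)
}

#' @export
as.dist.distance_matrix <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(unclass(m), diag = diag, upper = upper)
}

#' Write / read a distance matrix as square TSV
#' @param dm a `distance_matrix`.
#' @param path output file.
#' @export
write_distance_matrix <- function(dm, path) {
  df <- data.frame(sample_id = rownames(dm), unclass(dm),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_provenance(path, "write_distance_matrix", list(n = nrow(dm)))
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  distance_matrix(m)
}

# Shared wrapper around vegan::vegdist; pairs of all-empty samples get
# distance 0 (vegdist leaves them NaN).
vegdist_dm <- function(table, method, binary = FALSE) {
  x <- t(unclass(as_feature_table(table)))
  # empty samples are legal here (distance 0 between two empty samples);
  # vegdist warns about them and returns NaN, which we overwrite below
  d <- suppressWarnings(vegan::vegdist(x, method = method, binary = binary))
  m <- as.matrix(d)
  m[is.nan(m)] <- 0
  distance_matrix(m)
}

#' Jaccard distance between samples
#'
#' Presence/absence Jaccard: 1 - |intersection| / |union| of the presence
#' sets; 0 when both samples are empty.
#'
#' @param table a feature table.
#' @return a `distance_matrix`.
#' @export
jaccard <- function(table) vegdist_dm(table, "jaccard", binary = TRUE)

#' Bray-Curtis dissimilarity between samples
#'
#' `sum |x_i - y_i| / sum (x_i + y_i)`; 0 when both samples are empty.
#'
#' @param table a feature table.
#' @return a `distance_matrix`.
#' @export
bray_curtis <- function(table) vegdist_dm(table, "bray")

#' Unweighted UniFrac distance
#'
#' Fraction of the branch length spanned by the union of two samples'
#' root-to-tip paths that is unique to one of them. Computed by a single
#' post-order pass accumulating per-sample subtree sums; a root edge, were
#' one present, carries every sample and contributes nothing unique.
#'
#' @param table a feature table whose nonzero features are tips of `tree`.
#' @param tree a rooted `phylo` tree with branch lengths.
#' @return a `distance_matrix`.
#' @export
unweighted_unifrac <- function(table, tree) {
  table <- as_feature_table(table)
  check_tips(table, tree)
  acc <- edge_accumulate(unclass(table), tree)
  pres <- acc$props > 0
  n <- ncol(table)
  len <- acc$lengths
  m <- matrix(0, n, n, dimnames = list(colnames(table), colnames(table)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      a <- pres[, i]; b <- pres[, j]
      union_len <- sum(len[a | b])
      m[i, j] <- m[j, i] <-
        if (union_len == 0) 0 else sum(len[xor(a, b)]) / union_len
    }
  }
  distance_matrix(m)
}

#' Generalized UniFrac distance
#'
#' Abundance-weighted phylogenetic dissimilarity interpolating between
#' presence-oriented (alpha = 0) and fully proportion-weighted
#' (alpha = 1) variants:
#' \deqn{d^{(\alpha)}(x,y) = \frac{\sum_b \ell_b (p_{xb}+p_{yb})^\alpha
#'   \frac{|p_{xb}-p_{yb}|}{p_{xb}+p_{yb}}}{\sum_b \ell_b
#'   (p_{xb}+p_{yb})^\alpha}}
#' where \eqn{p_{sb}} is the proportion of sample \eqn{s} descending from
#' branch \eqn{b} and the sums run over branches with
#' \eqn{p_{xb}+p_{yb} > 0}. At alpha = 1 this is the weighted-normalized
#' UniFrac.
#'
#' @param table a feature table; samples are normalized internally to
#'   proportions (a sample with zero total is an error).
#' @param tree a rooted `phylo` tree with branch lengths.
#' @param alpha weighting exponent in `[0, 1]`; default 0.5.
#' @return a `distance_matrix`.
#' @export
generalized_unifrac <- function(table, tree, alpha = 0.5) {
  table <- as_feature_table(table)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    stop("'alpha' must be a single value in [0, 1]")
  }
  totals <- colSums(table)
  if (any(totals == 0)) {
    stop("samples with zero total: ",
         paste(colnames(table)[totals == 0], collapse = ", "))
  }
  check_tips(table, tree)
  props <- sweep(unclass(table), 2L, totals, "/")
  acc <- edge_accumulate(props, tree)
  len <- acc$lengths
  p <- acc$props
  n <- ncol(table)
  m <- matrix(0, n, n, dimnames = list(colnames(table), colnames(table)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      px <- p[, i]; py <- p[, j]
      s <- px + py
      keep <- s > 0
      w <- len[keep] * s[keep]^alpha
      den <- sum(w)
      m[i, j] <- m[j, i] <-
        if (den == 0) 0 else sum(w * abs(px[keep] - py[keep]) / s[keep]) / den
    }
  }
  distance_matrix(m)
}
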