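#' Principal coordinate analysis (classical scaling)
#'
#' Double-centers `-D^2/2` and eigendecomposes. Coordinates are returned
#' for positive eigenvalues only, as eigenvector times the square root of
#' the eigenvalue; negative eigenvalues are reported (no correction is
#' applied) so embedding quality can be judged. `proportion_explained` is
#' computed over the positive eigenvalues.
#'
#' @param dm a `distance_matrix`.
#' @return object of class `ordination`: list with `coordinates`
#'   (samples x axes), `eigenvalues` (all, descending) and
#'   `proportion_explained` (per retained axis).
#' @export
pcoa <- function(dm) {
  n <- nrow(dm)
  if (n < 2L) stop("need at least 2 samples for ordination")
  d2 <- unclass(dm)^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% d2 %*% J
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  vals <- eig$values
  tol <- max(abs(vals)) * 1e-10
  pos <- vals > tol
  coords <- eig$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(vals[pos]), nrow = sum(pos))
  rownames(coords) <- rownames(dm)
  if (ncol(coords)) colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  structure(list(
    coordinates = coords,
    eigenvalues = vals,
    proportion_explained = if (any(pos)) vals[pos] / sum(vals[pos]) else numeric()
  ), class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("ordination: %d samples, %d retained axes\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  if (length(x$proportion_explained)) {
    cat("proportion explained:",
        paste(sprintf("%.1f%%", 100 * utils::head(x$proportion_explained, 5)),
              collapse = " "), "\n")
  }
  invisible(x)
}

#' Write an ordination: coordinates TSV plus eigenvalue JSON
#' @param ord an `ordination`.
#' @param prefix path prefix; writes `<prefix>_coords.tsv` and
#'   `<prefix>_eigen.json`.
#' @export
write_ordination <- function(ord, prefix) {
  cpath <- paste0(prefix, "_coords.tsv")
  df <- data.frame(sample_id = rownames(ord$coordinates), ord$coordinates,
                   check.names = FALSE)
  utils::write.table(df, cpath, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(eigenvalues = ord$eigenvalues,
         proportion_explained = ord$proportion_explained),
    paste0(prefix, "_eigen.json"), digits = NA)
  write_provenance(cpath, "write_ordination", list())
  invisible(prefix)
}

# one-way distance-based SS_within for a label vector, from the squared
# distance matrix
ss_within <- function(d2, labels) {
  tot <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    tot <- tot + sum(d2[idx, idx]) / (2 * length(idx))
  }
  tot
}

#' One-way PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance following Anderson's
#' distance-based one-way partition:
#' `SS_total = sum_{i<j} d_ij^2 / n`, `SS_within` summed per group
#' analogously, and `F = (SS_between/(g-1)) / (SS_within/(n-g))`. The
#' p-value uses the `(1 + #{F* >= F}) / (1 + n_permutations)` convention
#' and is deterministic given `seed`.
#'
#' @param dm a `distance_matrix`.
#' @param grouping named vector (names = sample ids) or vector aligned
#'   with the samples of `dm`; at least two groups.
#' @param n_permutations number of label permutations (default 999).
#' @param seed integer seed.
#' @return object of class `permanova`: list with `pseudo_F`, `p_value`,
#'   `n_permutations`, `group_sizes`.
#' @export
permanova <- function(dm, grouping, n_permutations = 999L, seed = 1L) {
  n <- nrow(dm)
  if (!is.null(names(grouping))) {
    missing <- setdiff(rownames(dm), names(grouping))
    if (length(missing)) stop("no group for samples: ",
                              paste(missing, collapse = ", "))
    grouping <- grouping[rownames(dm)]
  }
  if (length(grouping) != n) stop("'grouping' must cover every sample")
  labels <- as.character(grouping)
  sizes <- table(labels)
  g <- length(sizes)
  if (g < 2L) stop("need at least 2 groups")
  if (n_permutations < 1L) stop("'n_permutations' must be >= 1")
  d2 <- unclass(dm)^2
  ss_tot <- sum(d2) / (2 * n)
  df_b <- g - 1L
  df_w <- n - g
  f_stat <- function(lab) {
    ssw <- ss_within(d2, lab)
    ((ss_tot - ssw) / df_b) / (ssw / df_w)
  }
  f_obs <- f_stat(labels)
  f_perm <- with_seed(seed, {
    vapply(seq_len(n_permutations),
           function(b) f_stat(labels[sample.int(n)]), numeric(1))
  })
  p <- (1 + sum(f_perm >= f_obs)) / (1 + n_permutations)
  structure(list(pseudo_F = f_obs, p_value = p,
                 n_permutations = as.integer(n_permutations),
                 group_sizes = as.list(sizes)),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$p_value, x$n_permutations))
  invisible(x)
}

#' Write a PERMANOVA result as JSON
#' @param result a `permanova` object.
#' @param path output file.
#' @export
write_permanova <- function(result, path) {
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE, digits = NA)
  write_provenance(path, "write_permanova", list())
  invisible(path)
}
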