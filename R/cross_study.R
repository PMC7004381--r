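#' Read a compartment pairing file
#'
#' Three-column TSV: `sample_a`, `sample_b`, `combined_id`.
#'
#' @param path pairing TSV.
#' @return data.frame with those three columns.
#' @export
read_pairing <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("sample_a", "sample_b", "combined_id")
  df
}

#' Combine paired plant-compartment samples
#'
#' Replaces each pair of samples (e.g. an epiphytic and an endophytic
#' fraction of the same plant) by one combined sample whose counts are
#' the element-wise sum, representing the whole plant-associated
#' community. Total reads are conserved exactly.
#'
#' @param table a feature table.
#' @param pairing data.frame with `sample_a`, `sample_b`, `combined_id`;
#'   each sample may appear in at most one pair and combined ids must be
#'   unique.
#' @param unpaired `"passthrough"` keeps unpaired samples unchanged,
#'   `"error"` fails when the pairing references samples missing from the
#'   table.
#' @return a `feature_table` of combined (plus any passthrough) samples.
#' @export
combine_compartments <- function(table, pairing,
                                 unpaired = c("passthrough", "error")) {
  unpaired <- match.arg(unpaired)
  table <- as_feature_table(table)
  paired_ids <- c(pairing$sample_a, pairing$sample_b)
  if (anyDuplicated(paired_ids)) stop("a sample appears in more than one pair")
  if (anyDuplicated(pairing$combined_id)) stop("combined ids must be unique")
  missing <- setdiff(paired_ids, colnames(table))
  if (length(missing) && unpaired == "error") {
    stop("pairing references missing samples: ",
         paste(missing, collapse = ", "))
  }
  tab_m <- unclass(table)
  cols <- list()
  for (i in seq_len(nrow(pairing))) {
    a <- pairing$sample_a[i]; b <- pairing$sample_b[i]
    if (!a %in% colnames(tab_m) || !b %in% colnames(tab_m)) next
    cols[[pairing$combined_id[i]]] <- tab_m[, a] + tab_m[, b]
  }
  rest <- setdiff(colnames(tab_m), paired_ids)
  for (r in rest) cols[[r]] <- tab_m[, r]
  if (!length(cols)) stop("no samples left after combining")
  m <- do.call(cbind, cols)
  rownames(m) <- rownames(tab_m)
  feature_table(m)
}

#' Genus counts per phylum and sample
#'
#' For each sample and phylum, the number of distinct assigned genera
#' (keyed by full lineage, so a genus name appearing under two phyla
#' counts separately) observed with count > 0. Unknown phylum names are
#' allowed and yield zeros.
#'
#' @param table a feature table at genus rank or finer.
#' @param taxonomy a `taxonomy_map`.
#' @param phyla character vector of phylum names (columns of the result).
#' @return integer matrix, samples x phyla.
#' @export
genus_counts_by_phylum <- function(table, taxonomy, phyla) {
  table <- as_feature_table(table)
  ranks <- lookup_ranks(table, taxonomy)
  assigned <- ranks[, "genus"] != ""
  genus_key <- format_lineage(ranks, depth = 6L)
  out <- matrix(0L, nrow = ncol(table), ncol = length(phyla),
                dimnames = list(colnames(table), phyla))
  for (p in seq_along(phyla)) {
    sel <- assigned & ranks[, "phylum"] == phyla[p]
    if (!any(sel)) next
    sub <- unclass(table)[sel, , drop = FALSE]
    keys <- genus_key[sel]
    for (s in seq_len(ncol(sub))) {
      out[s, p] <- length(unique(keys[sub[, s] > 0]))
    }
  }
  out
}

#' Dunn's test with BH adjustment and compact letters
#'
#' Joint ranking of all values with tie correction; pairwise Dunn z
#' statistics, two-sided p-values, BH adjustment across pairs, and a
#' compact letter display (insert-absorb) in which two groups share a
#' letter iff their adjusted p-value is >= `alpha`.
#'
#' @param values named list of numeric vectors, >= 2 groups with >= 2
#'   values each.
#' @param alpha significance level for the letter display (default 0.05).
#' @return object of class `dunn_result`: list with `pairs` (data.frame:
#'   group_a, group_b, z, p, p_adjust) and `letters` (named character).
#' @export
dunn_test <- function(values, alpha = 0.05) {
  if (length(values) < 2L) stop("need at least 2 groups")
  if (is.null(names(values))) names(values) <- paste0("g", seq_along(values))
  sizes <- vapply(values, length, integer(1))
  if (any(sizes < 2L)) stop("every group needs at least 2 values")
  all_vals <- unlist(values, use.names = FALSE)
  n <- length(all_vals)
  r <- rank(all_vals)
  grp <- rep(names(values), sizes)
  mean_rank <- tapply(r, factor(grp, levels = names(values)), mean)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))

  combos <- utils::combn(names(values), 2L)
  z <- p <- numeric(ncol(combos))
  for (i in seq_len(ncol(combos))) {
    a <- combos[1L, i]; b <- combos[2L, i]
    se <- sqrt((n * (n + 1) / 12 - tie_term) *
                 (1 / sizes[[a]] + 1 / sizes[[b]]))
    z[i] <- (mean_rank[[a]] - mean_rank[[b]]) / se
    p[i] <- 2 * stats::pnorm(abs(z[i]), lower.tail = FALSE)
  }
  p_adj <- stats::p.adjust(p, "BH")
  pairs <- data.frame(group_a = combos[1L, ], group_b = combos[2L, ],
                      z = z, p = p, p_adjust = p_adj,
                      stringsAsFactors = FALSE)

  sig <- matrix(FALSE, length(values), length(values),
                dimnames = list(names(values), names(values)))
  for (i in seq_len(nrow(pairs))) {
    s <- pairs$p_adjust[i] < alpha
    sig[pairs$group_a[i], pairs$group_b[i]] <- s
    sig[pairs$group_b[i], pairs$group_a[i]] <- s
  }
  letters_out <- compact_letters(sig, order_by = rank(-unlist(mean_rank)))
  structure(list(pairs = pairs, letters = letters_out, alpha = alpha),
            class = "dunn_result")
}

#' @export
print.dunn_result <- function(x, ...) {
  print(x$pairs)
  cat("letters:", paste(names(x$letters), x$letters, sep = "=",
                        collapse = " "), "\n")
  invisible(x)
}

#' Compact letter display by insert-absorb
#'
#' Assigns letters so that two groups share a letter iff they are not
#' significantly different. Groups are processed in the given order
#' (default as supplied); letters are alphabetical.
#'
#' @param sig logical matrix of pairwise significance (TRUE = groups
#'   differ), symmetric with group names as dimnames.
#' @param order_by optional ranking used to order the groups before
#'   assignment (e.g. by mean rank).
#' @return named character vector of letter strings per group.
#' @export
compact_letters <- function(sig, order_by = NULL) {
  groups <- rownames(sig)
  ord <- if (is.null(order_by)) seq_along(groups) else order(order_by)
  groups <- groups[ord]
  empty_col <- stats::setNames(rep(FALSE, length(groups)), groups)
  # columns of `cols` are letters: logical membership per group
  first <- empty_col; first[groups[1]] <- TRUE
  cols <- list(first)
  absorb <- function(cols) {
    keep <- rep(TRUE, length(cols))
    for (i in seq_along(cols)) {
      for (j in seq_along(cols)) {
        if (i == j || !keep[j] || !keep[i]) next
        subset_ij <- all(!cols[[i]] | cols[[j]])
        if (subset_ij && (any(cols[[i]] != cols[[j]]) || i > j)) {
          keep[i] <- FALSE
          break
        }
      }
    }
    cols[keep]
  }
  for (g in groups[-1]) {
    placed <- FALSE
    new_cols <- list()
    for (i in seq_along(cols)) {
      members <- names(cols[[i]])[cols[[i]]]
      conflicts <- sig[g, members]
      if (!any(conflicts)) {
        cols[[i]][g] <- TRUE
        placed <- TRUE
      } else if (!all(conflicts)) {
        # duplicate the column keeping only the members compatible with g
        nc <- empty_col
        nc[members[!conflicts]] <- TRUE
        nc[g] <- TRUE
        new_cols <- c(new_cols, list(nc))
        placed <- TRUE
      }
    }
    if (!placed) {
      nc <- empty_col; nc[g] <- TRUE
      new_cols <- list(nc)
    }
    cols <- absorb(c(cols, new_cols))
  }
  letter_names <- letters[seq_along(cols)]
  vapply(rownames(sig), function(g) {
    paste(letter_names[vapply(cols, function(cc) cc[g], logical(1))],
          collapse = "")
  }, character(1))
}

#' Write Dunn results as TSV with letters
#' @param result a `dunn_result`.
#' @param path output file.
#' @export
write_dunn <- function(result, path) {
  utils::write.table(result$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(as.list(result$letters),
                       paste0(path, ".letters.json"), auto_unbox = TRUE)
  write_provenance(path, "write_dunn", list(alpha = result$alpha))
  invisible(path)
}

# all permutations of 1..n (n <= 9) as a matrix, one permutation per row
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (pos in seq_len(n)) {
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- append(sub[i, ], n, after = pos - 1L)
      row <- row + 1L
    }
  }
  out
}

#' Spearman correlation of taxa abundance between two sample groups
#'
#' Computes each feature's median clr within the two groups and the
#' Spearman rank correlation between the two per-feature vectors. The
#' p-value uses exact permutation enumeration for fewer than 10 features
#' and the t-approximation otherwise.
#'
#' @param clr a `clr_distribution`.
#' @param group_a,group_b character vectors of sample ids.
#' @return list with `rho`, `p`, `n_features`.
#' @export
spearman_group_correlation <- function(clr, group_a, group_b) {
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty")
  ca <- clr_subset(clr, samples = group_a)
  cb <- clr_subset(clr, samples = group_b)
  va <- feature_median_clr(ca)
  vb <- feature_median_clr(cb)
  n <- length(va)
  if (n < 3L) stop("need at least 3 shared features")
  if (length(unique(va)) == 1L || length(unique(vb)) == 1L) {
    stop("constant median-clr vector; Spearman rho undefined")
  }
  ra <- rank(va); rb <- rank(vb)
  rho <- stats::cor(ra, rb)
  if (n < 10L) {
    perms <- all_permutations(n)
    rho_perm <- apply(perms, 1L, function(idx) stats::cor(ra, rb[idx]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(t), n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p = p, n_features = n)
}
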