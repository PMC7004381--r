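#' Monte-Carlo Dirichlet CLR transformation
#'
#' For every sample, draws `n_instances` probability vectors from
#' Dirichlet(counts + 0.5) and converts each to centered log-ratios on
#' the log2 scale: `clr_i = log2(p_i) - mean_j log2(p_j)`. The 0.5 prior
#' and log base 2 mean clr differences read directly as log2
#' fold-changes. Every (sample, instance) clr vector sums to zero.
#'
#' @param table a feature table; every sample total must be > 0.
#' @param n_instances number of Monte-Carlo instances (default 128).
#' @param seed integer seed.
#' @return object of class `clr_distribution`: list with `values`
#'   (features x samples x instances array), `feature_ids`, `sample_ids`,
#'   `n_instances`.
#' @export
clr_transform <- function(table, n_instances = 128L, seed = 1L) {
  table <- as_feature_table(table)
  if (n_instances < 1L) stop("'n_instances' must be >= 1")
  totals <- colSums(table)
  if (any(totals == 0)) {
    stop("samples with zero total: ",
         paste(colnames(table)[totals == 0], collapse = ", "))
  }
  nf <- nrow(table); ns <- ncol(table); k <- as.integer(n_instances)
  vals <- with_seed(seed, {
    arr <- array(NA_real_, dim = c(nf, ns, k))
    shape <- unclass(table) + 0.5
    for (s in seq_len(ns)) {
      g <- matrix(stats::rgamma(nf * k, shape = shape[, s]), nrow = nf)
      lg <- log2(g)
      arr[, s, ] <- lg - rep(colMeans(lg), each = nf)
    }
    arr
  })
  dimnames(vals) <- list(rownames(table), colnames(table), NULL)
  structure(list(values = vals, feature_ids = rownames(table),
                 sample_ids = colnames(table), n_instances = k),
            class = "clr_distribution")
}

#' @export
print.clr_distribution <- function(x, ...) {
  cat(sprintf("clr_distribution: %d features x %d samples x %d instances (log2)\n",
              length(x$feature_ids), length(x$sample_ids), x$n_instances))
  invisible(x)
}

#' Subset a clr distribution by features and/or samples
#' @param clr a `clr_distribution`.
#' @param features,samples character vectors (default: keep all).
#' @return a `clr_distribution`.
#' @export
clr_subset <- function(clr, features = NULL, samples = NULL) {
  f <- if (is.null(features)) clr$feature_ids else features
  s <- if (is.null(samples)) clr$sample_ids else samples
  bad_f <- setdiff(f, clr$feature_ids)
  bad_s <- setdiff(s, clr$sample_ids)
  if (length(bad_f)) stop("unknown features: ", paste(bad_f, collapse = ", "))
  if (length(bad_s)) stop("unknown samples: ", paste(bad_s, collapse = ", "))
  structure(list(values = clr$values[f, s, , drop = FALSE],
                 feature_ids = f, sample_ids = s,
                 n_instances = clr$n_instances),
            class = "clr_distribution")
}

#' Median clr over a feature/sample subset
#'
#' The median over all (feature, sample, instance) values in the subset;
#' the basis of every "median clr" abundance statement in the package.
#'
#' @param clr a `clr_distribution`.
#' @param features,samples optional subsets (default all).
#' @return a single numeric value.
#' @export
median_clr <- function(clr, features = NULL, samples = NULL) {
  sub <- clr_subset(clr, features, samples)
  if (length(sub$values) == 0L) stop("empty subset")
  stats::median(sub$values)
}

# per-feature median clr over given samples (across instances)
feature_median_clr <- function(clr, samples = NULL) {
  sub <- if (is.null(samples)) clr else clr_subset(clr, samples = samples)
  apply(sub$values, 1L, stats::median)
}

# per-(feature, sample) median clr across instances
sample_median_clr <- function(clr) {
  apply(clr$values, c(1L, 2L), stats::median)
}

# Vectorized Welch's t-test p-values across rows of two matrices
welch_p <- function(xa, xb) {
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  p[se2 == 0] <- 1
  p
}

# Vectorized two-sided Wilcoxon rank-sum p-values across rows; exact
# distribution when both groups < 8 and untied, tie-corrected normal
# approximation otherwise.
rank_sum_p <- function(xa, xb) {
  na <- ncol(xa); nb <- ncol(xb); n <- na + nb
  x <- cbind(xa, xb)
  exact_ok <- na < 8L && nb < 8L
  vapply(seq_len(nrow(x)), function(i) {
    r <- rank(x[i, ])
    ties <- table(r)
    if (exact_ok && all(ties == 1L)) {
      w <- sum(r[seq_len(na)]) - na * (na + 1) / 2
      return(min(1, 2 * min(stats::pwilcox(w, na, nb),
                            stats::pwilcox(w - 1, na, nb,
                                           lower.tail = FALSE))))
    }
    w <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    mu <- na * nb / 2
    tie_term <- sum(ties^3 - ties) / ((n) * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) return(1)
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    2 * stats::pnorm(abs(z), lower.tail = FALSE)
  }, numeric(1))
}

#' Pairwise differential abundance on a clr distribution
#'
#' For each feature and Monte-Carlo instance, Welch's t and Wilcoxon
#' rank-sum tests compare the per-sample clr values across the two
#' groups; p-values are BH-adjusted across features within each instance
#' and averaged over instances (`we.eBH`, `wi.eBH`). Effect sizes follow
#' the Monte-Carlo pairing scheme: per instance, samples are randomly
#' paired between groups (with replacement when sizes differ) giving
#' between-group differences, and within each group giving within-group
#' differences; `diff.btw` is the median between-group difference
#' (group B minus group A), `diff.win` the median of the larger
#' within-group absolute difference, and `effect` the median of the
#' pointwise ratio.
#'
#' @param clr a `clr_distribution`.
#' @param grouping named vector mapping each sample to one of two levels;
#'   both groups need >= 2 samples. The first level in sort order is
#'   group A (the reference: positive effects mean higher in group B).
#' @param seed integer seed for the pairing scheme.
#' @return data.frame of class `diff_abund` with columns `feature_id`,
#'   `rab.win.<A>`, `rab.win.<B>`, `diff.btw`, `diff.win`, `effect`,
#'   `we.ep`, `we.eBH`, `wi.ep`, `wi.eBH`.
#' @export
diff_abund_pairwise <- function(clr, grouping, seed = 1L) {
  if (is.null(names(grouping))) stop("'grouping' must be named by sample id")
  grouping <- grouping[clr$sample_ids]
  if (anyNA(grouping)) stop("grouping missing for some samples")
  levs <- sort(unique(as.character(grouping)))
  if (length(levs) != 2L) stop("grouping must have exactly two levels")
  ia <- which(grouping == levs[1L])
  ib <- which(grouping == levs[2L])
  if (length(ia) < 2L || length(ib) < 2L) {
    stop("both groups need at least 2 samples")
  }
  nf <- length(clr$feature_ids); k <- clr$n_instances
  na <- length(ia); nb <- length(ib)
  npair <- max(na, nb)

  we_mat <- matrix(NA_real_, nf, k)
  wi_mat <- matrix(NA_real_, nf, k)
  we_bh <- matrix(NA_real_, nf, k)
  wi_bh <- matrix(NA_real_, nf, k)
  btw <- array(NA_real_, c(nf, npair, k))
  win <- array(NA_real_, c(nf, npair, k))

  with_seed(seed, {
    for (m in seq_len(k)) {
      xa <- clr$values[, ia, m, drop = FALSE][, , 1L, drop = TRUE]
      xb <- clr$values[, ib, m, drop = FALSE][, , 1L, drop = TRUE]
      if (nf == 1L) { xa <- matrix(xa, 1L); xb <- matrix(xb, 1L) }
      we_mat[, m] <- welch_p(xa, xb)
      wi_mat[, m] <- rank_sum_p(xa, xb)
      we_bh[, m] <- stats::p.adjust(we_mat[, m], "BH")
      wi_bh[, m] <- stats::p.adjust(wi_mat[, m], "BH")
      pa <- sample.int(na, npair, replace = npair > na)
      pb <- sample.int(nb, npair, replace = npair > nb)
      btw[, , m] <- xb[, pb, drop = FALSE] - xa[, pa, drop = FALSE]
      wa <- abs(xa[, sample.int(na, npair, replace = TRUE), drop = FALSE] -
                  xa[, sample.int(na, npair, replace = TRUE), drop = FALSE])
      wb <- abs(xb[, sample.int(nb, npair, replace = TRUE), drop = FALSE] -
                  xb[, sample.int(nb, npair, replace = TRUE), drop = FALSE])
      win[, , m] <- pmax(wa, wb)
    }
  })

  ratio <- btw / win
  ratio[btw == 0] <- 0
  ratio[win == 0 & btw != 0] <- sign(btw[win == 0 & btw != 0]) * Inf

  res <- data.frame(
    feature_id = clr$feature_ids,
    rab_a = apply(clr$values[, ia, , drop = FALSE], 1L, stats::median),
    rab_b = apply(clr$values[, ib, , drop = FALSE], 1L, stats::median),
    diff.btw = apply(btw, 1L, stats::median),
    diff.win = apply(win, 1L, stats::median),
    effect = apply(ratio, 1L, stats::median),
    we.ep = rowMeans(we_mat),
    we.eBH = rowMeans(we_bh),
    wi.ep = rowMeans(wi_mat),
    wi.eBH = rowMeans(wi_bh),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  names(res)[2:3] <- paste0("rab.win.", levs)
  attr(res, "groups") <- levs
  class(res) <- c("diff_abund", "data.frame")
  res
}

#' Write differential-abundance results as TSV
#' @param results a `diff_abund` data.frame.
#' @param path output file.
#' @export
write_diff_abund <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_provenance(path, "write_diff_abund", list(n = nrow(results)))
  invisible(path)
}

#' Multi-factor differential abundance (Kruskal-Wallis + linear model)
#'
#' For each feature and each design factor (main effects, up to 3
#' factors): (a) a Kruskal-Wallis test on per-sample median clr across
#' the factor's levels; (b) a Gaussian main-effects least-squares model
#' fitted to every Monte-Carlo instance with a drop-one F-test per
#' factor, whose BH-adjusted p-values are averaged over instances.
#' Both families are BH-adjusted across features.
#'
#' @param clr a `clr_distribution`.
#' @param design data.frame of factors, one row per sample, with
#'   rownames (or a `sample_id` column) matching the clr samples.
#' @return data.frame with per feature and factor: `kw.p`, `kw.BH`,
#'   `glm.ep`, `glm.eBH` (columns suffixed by factor name).
#' @export
diff_abund_factors <- function(clr, design) {
  if (!is.null(design$sample_id)) {
    rownames(design) <- design$sample_id
    design$sample_id <- NULL
  }
  design <- design[clr$sample_ids, , drop = FALSE]
  if (anyNA(design)) stop("design missing for some samples")
  if (ncol(design) < 1L || ncol(design) > 3L) {
    stop("design must have 1-3 factors")
  }
  design[] <- lapply(design, factor)
  for (f in names(design)) {
    if (nlevels(design[[f]]) < 2L) stop("factor '", f, "' has a single level")
  }
  nf <- length(clr$feature_ids); k <- clr$n_instances
  med <- sample_median_clr(clr)  # features x samples

  out <- data.frame(feature_id = clr$feature_ids, stringsAsFactors = FALSE)
  x_full <- stats::model.matrix(~ ., data = design)
  q_full <- qr.Q(qr(x_full))
  df_res <- nrow(x_full) - ncol(x_full)
  assign_full <- attr(stats::model.matrix(~ ., data = design), "assign")

  for (fi in seq_along(design)) {
    fname <- names(design)[fi]
    kw <- apply(med, 1L, function(v) {
      stats::kruskal.test(v, design[[fi]])$p.value
    })
    drop_cols <- which(assign_full == fi)
    q_red <- qr.Q(qr(x_full[, -drop_cols, drop = FALSE]))
    df_f <- length(drop_cols)
    glm_p <- matrix(NA_real_, nf, k)
    glm_bh <- matrix(NA_real_, nf, k)
    for (m in seq_len(k)) {
      y <- t(clr$values[, , m, drop = FALSE][, , 1L, drop = TRUE])
      if (nf == 1L) y <- matrix(y, ncol = 1L)
      tss <- colSums(y^2)
      rss_full <- tss - colSums((t(q_full) %*% y)^2)
      rss_red <- tss - colSums((t(q_red) %*% y)^2)
      fstat <- ((rss_red - rss_full) / df_f) / (rss_full / df_res)
      p <- stats::pf(fstat, df_f, df_res, lower.tail = FALSE)
      p[!is.finite(p)] <- 1
      glm_p[, m] <- p
      glm_bh[, m] <- stats::p.adjust(p, "BH")
    }
    out[[paste0("kw.p.", fname)]] <- kw
    out[[paste0("kw.BH.", fname)]] <- stats::p.adjust(kw, "BH")
    out[[paste0("glm.ep.", fname)]] <- rowMeans(glm_p)
    out[[paste0("glm.eBH.", fname)]] <- rowMeans(glm_bh)
  }
  out
}

#' Select significantly different taxa
#'
#' Applies the decision rule used throughout the analyses: expected
#' BH-adjusted Welch p below `p_threshold` and absolute effect size
#' above `effect_threshold`, annotated with the direction of change.
#'
#' @param results a `diff_abund` data.frame.
#' @param p_threshold default 0.05.
#' @param effect_threshold default 1.5.
#' @return data.frame of selected features with a `direction` column
#'   (`"positive"` = higher in group B).
#' @export
significant_taxa <- function(results, p_threshold = 0.05,
                             effect_threshold = 1.5) {
  if (p_threshold <= 0 || effect_threshold <= 0) {
    stop("thresholds must be positive")
  }
  sel <- results$we.eBH < p_threshold & abs(results$effect) > effect_threshold
  out <- results[sel, , drop = FALSE]
  out$direction <- ifelse(out$effect > 0, "positive", "negative")
  rownames(out) <- NULL
  out
}
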