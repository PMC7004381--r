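# Independent oracles: every routine here takes a different computational
# path from the package implementation it is checked against (explicit
# tip-set enumeration, direct formula evaluation, closed forms).

# Per-edge descendant sums via explicit clade tip enumeration
# (phangorn::Descendants), independent of the package's post-order pass.
oracle_edge_table <- function(tree, values) {
  desc <- phangorn::Descendants(tree, tree$edge[, 2], type = "tips")
  props <- t(vapply(desc, function(d) {
    tips <- intersect(tree$tip.label[d], rownames(values))
    if (!length(tips)) return(rep(0, ncol(values)))
    colSums(values[tips, , drop = FALSE])
  }, numeric(ncol(values))))
  if (ncol(values) == 1L) props <- matrix(props, ncol = 1L)
  list(lengths = tree$edge.length, props = props)
}

oracle_unweighted_unifrac <- function(table, tree) {
  et <- oracle_edge_table(tree, unclass(table))
  pres <- et$props > 0
  n <- ncol(table)
  m <- matrix(0, n, n, dimnames = list(colnames(table), colnames(table)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- pres[, i]; b <- pres[, j]
    u <- sum(et$lengths[a | b])
    m[i, j] <- if (u == 0) 0 else sum(et$lengths[a != b]) / u
  }
  m
}

oracle_generalized_unifrac <- function(table, tree, alpha) {
  props <- sweep(unclass(table), 2, colSums(table), "/")
  et <- oracle_edge_table(tree, props)
  n <- ncol(table)
  m <- matrix(0, n, n, dimnames = list(colnames(table), colnames(table)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- den <- 0
    for (b in seq_along(et$lengths)) {
      px <- et$props[b, i]; py <- et$props[b, j]
      if (px + py > 0) {
        num <- num + et$lengths[b] * (px + py)^alpha * abs(px - py) / (px + py)
        den <- den + et$lengths[b] * (px + py)^alpha
      }
    }
    m[i, j] <- if (den == 0) 0 else num / den
  }
  m
}

# weighted-normalized UniFrac, coded directly from its own formula
oracle_weighted_normalized_unifrac <- function(table, tree) {
  props <- sweep(unclass(table), 2, colSums(table), "/")
  et <- oracle_edge_table(tree, props)
  n <- ncol(table)
  m <- matrix(0, n, n, dimnames = list(colnames(table), colnames(table)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- sum(et$lengths * abs(et$props[, i] - et$props[, j]))
    den <- sum(et$lengths * (et$props[, i] + et$props[, j]))
    m[i, j] <- if (den == 0) 0 else num / den
  }
  m
}

oracle_faith_pd <- function(table, tree) {
  et <- oracle_edge_table(tree, unclass(table))
  stats::setNames(colSums(et$lengths * (et$props > 0)), colnames(table))
}

oracle_bray_curtis <- function(table) {
  x <- unclass(table)
  n <- ncol(x)
  m <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    tot <- sum(x[, i] + x[, j])
    m[i, j] <- if (tot == 0) 0 else sum(abs(x[, i] - x[, j])) / tot
  }
  m
}

# tie-corrected normal-approximation rank-sum z for two groups
oracle_rank_sum_z <- function(a, b) {
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n1)])
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  (w - n1 * (n + 1) / 2) / sqrt(sigma2)
}

# Spearman rho from the classical rank-difference formula (untied data)
oracle_spearman_rho <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}
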