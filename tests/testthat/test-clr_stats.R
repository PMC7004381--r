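test_that("clr instances satisfy the zero-sum and log-ratio identities", {
  set.seed(201)
  tab <- random_table(n_feat = 12, n_samp = 5, max_count = 100)
  clr <- clr_transform(tab, n_instances = 20, seed = 7)
  sums <- apply(clr$values, c(2, 3), sum)
  expect_true(max(abs(sums)) < 1e-9)
  # determinism
  clr2 <- clr_transform(tab, n_instances = 20, seed = 7)
  expect_identical(clr$values, clr2$values)
  # clr_i - clr_j equals the within-instance log2 proportion ratio:
  # differences of clr values across features are differences of log2 p
  v <- clr$values[, 1, 1]
  expect_equal(v[1] - v[2], (v[1] - mean(v)) - (v[2] - mean(v)))
  expect_error(clr_transform(feature_table(
    matrix(0L, 2, 1, dimnames = list(c("a", "b"), "s"))), 8), "zero total")
})

test_that("features with equal counts get equal median clr up to Monte-Carlo error", {
  m <- matrix(c(50L, 50L, 10L, 200L), 4, 1,
              dimnames = list(paste0("f", 1:4), "s1"))
  clr <- clr_transform(feature_table(m), n_instances = 1024, seed = 3)
  med <- apply(clr$values[, 1, ], 1, median)
  expect_lt(abs(med[1] - med[2]), 0.05)
  expect_gt(med[4], med[3])
})

test_that("median_clr equals a flatten-and-sort oracle on random subsets", {
  set.seed(211)
  tab <- random_table(n_feat = 8, n_samp = 6)
  clr <- clr_transform(tab, n_instances = 16, seed = 1)
  for (i in 1:5) {
    f <- sample(clr$feature_ids, sample(1:4, 1))
    s <- sample(clr$sample_ids, sample(1:3, 1))
    expect_equal(median_clr(clr, f, s),
                 median(sort(as.vector(clr$values[f, s, ]))))
  }
  expect_error(clr_subset(clr, features = "missing"), "unknown features")
  # single value subsets return that value
  one <- clr$values[2, 3, ] # all instances of one cell
  expect_equal(median_clr(clr, clr$feature_ids[2], clr$sample_ids[3]),
               median(one))
})

test_that("scale invariance: clr medians shift little under depth scaling", {
  set.seed(221)
  comp <- rgamma(20, 2); comp <- comp / sum(comp)
  base <- as.integer(round(comp * 1e4))
  m <- cbind(s1 = base, s2 = base * 5L)
  rownames(m) <- paste0("f", 1:20)
  clr <- clr_transform(feature_table(m), n_instances = 128, seed = 5)
  shift <- apply(clr$values[, 1, ], 1, median) -
    apply(clr$values[, 2, ], 1, median)
  expect_lt(max(abs(shift)), 0.05)
})

test_that("duplicate samples give zero between-group difference and effect", {
  set.seed(231)
  half <- random_table(n_feat = 10, n_samp = 3, max_count = 80)
  m <- cbind(unclass(half), unclass(half))
  colnames(m) <- paste0("s", 1:6)
  tab <- feature_table(m)
  k <- 8
  clr <- clr_transform(tab, n_instances = k, seed = 2)
  # force group B's clr values to literally duplicate group A's
  clr$values[, 4:6, ] <- clr$values[, 1:3, ]
  grp <- setNames(rep(c("A", "B"), each = 3), colnames(tab))
  da <- diff_abund_pairwise(clr, grp, seed = 9)
  expect_true(all(abs(da$diff.btw) < 1e-12))
  expect_true(all(da$effect == 0))
})

test_that("effect is antisymmetric under group swap; eBH invariant", {
  set.seed(241)
  tg <- two_group_table(n_feat = 15, n_per_group = 6, depth = 2e3,
                        shift_feature = 1, shift_fold = 8)
  clr <- clr_transform(tg$table, n_instances = 32, seed = 4)
  da_ab <- diff_abund_pairwise(clr, tg$grouping, seed = 11)
  swapped <- setNames(c(A = "B", B = "A")[tg$grouping], names(tg$grouping))
  # same pairing seed, reversed roles
  da_ba <- diff_abund_pairwise(clr, swapped, seed = 11)
  expect_equal(da_ab$we.eBH, da_ba$we.eBH, tolerance = 1e-12)
  expect_equal(da_ab$wi.eBH, da_ba$wi.eBH, tolerance = 1e-12)
  expect_equal(sign(da_ab$effect[1]), -sign(da_ba$effect[1]))
  expect_gt(abs(da_ab$effect[1]), 1.5)
  expect_true(all(da_ab$diff.win > 0))
})

test_that("significant_taxa applies the p/effect rule monotonically", {
  res <- data.frame(feature_id = c("a", "b", "c"),
                    effect = c(2.0, 1.2, -3.0),
                    we.eBH = c(0.01, 0.01, 0.2))
  sel <- significant_taxa(res)
  expect_identical(sel$feature_id, "a")
  expect_identical(sel$direction, "positive")
  # raising the effect threshold never adds features
  set.seed(251)
  for (i in 1:10) {
    rr <- data.frame(feature_id = paste0("f", 1:20),
                     effect = rnorm(20, 0, 2), we.eBH = runif(20))
    lo <- significant_taxa(rr, effect_threshold = 1)$feature_id
    hi <- significant_taxa(rr, effect_threshold = 2)$feature_id
    expect_true(all(hi %in% lo))
  }
  expect_error(significant_taxa(res, p_threshold = 0), "positive")
})

test_that("BH adjustment inside diff_abund is monotone and above raw p", {
  set.seed(261)
  tg <- two_group_table(n_feat = 25, n_per_group = 5, depth = 1e3)
  clr <- clr_transform(tg$table, n_instances = 8, seed = 6)
  da <- diff_abund_pairwise(clr, tg$grouping, seed = 6)
  expect_true(all(da$we.eBH >= da$we.ep - 1e-12))
  expect_true(all(da$wi.eBH >= da$wi.ep - 1e-12))
  expect_true(all(da$we.eBH <= 1 & da$we.eBH >= 0))
})

test_that("factor model calibrates under the null and detects a planted shift", {
  set.seed(271)
  # null: random factor levels -> few rejections
  rejections <- replicate(20, {
    tg <- two_group_table(n_feat = 20, n_per_group = 6, depth = 5e3)
    clr <- clr_transform(tg$table, n_instances = 8,
                         seed = sample.int(1e6, 1))
    design <- data.frame(sample_id = colnames(tg$table),
                         f1 = sample(rep(c("x", "y"), 6)),
                         f2 = sample(rep(c("u", "v", "w"), 4)))
    res <- diff_abund_factors(clr, design)
    c(mean(res$glm.eBH.f1 < 0.05), mean(res$kw.BH.f1 < 0.05))
  })
  expect_lte(mean(rejections[1, ]), 0.05)
  expect_lte(mean(rejections[2, ]), 0.05)
  # a +3 clr shift for one level of f1 is detected
  hits <- replicate(10, {
    tg <- two_group_table(n_feat = 20, n_per_group = 10, depth = 5e3,
                          shift_feature = 1, shift_fold = 8)
    clr <- clr_transform(tg$table, n_instances = 8,
                         seed = sample.int(1e6, 1))
    design <- data.frame(sample_id = colnames(tg$table),
                         f1 = rep(c("x", "y"), each = 10))
    res <- diff_abund_factors(clr, design)
    res$glm.eBH.f1[1] < 0.05
  })
  expect_gte(mean(hits), 0.9)
  # identical factors give identical p-values
  tg <- two_group_table(n_feat = 10, n_per_group = 5, depth = 1e3)
  clr <- clr_transform(tg$table, n_instances = 4, seed = 3)
  design <- data.frame(sample_id = colnames(tg$table),
                       f1 = rep(c("x", "y"), each = 5))
  r1 <- diff_abund_factors(clr, design)
  design2 <- design; names(design2)[2] <- "f2"
  r2 <- diff_abund_factors(clr, design2)
  expect_equal(r1$glm.eBH.f1, r2$glm.eBH.f2)
  expect_equal(r1$kw.p.f1, r2$kw.p.f2)
  design$bad <- "only_level"
  expect_error(diff_abund_factors(clr, design), "single level")
})
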