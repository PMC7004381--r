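test_that("observed features counts nonzero features per sample", {
  m <- matrix(c(3, 0, 1, 0, 0, 0), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  expect_equal(unname(observed_features(feature_table(m))), c(2, 0))
  # rarefaction can only lose features
  set.seed(11)
  tab <- random_table(n_feat = 30, n_samp = 4, max_count = 200)
  r <- rarefy(tab, min(colSums(tab)), seed = 5)
  expect_true(all(observed_features(r) <= observed_features(tab)[colnames(r)]))
})

test_that("Faith's PD follows the union-of-root-paths convention", {
  tree <- balanced_tree()
  tab <- presence_table(list(all = c("A", "B", "C", "D"), onlyA = "A",
                             none = character()),
                        c("A", "B", "C", "D"))
  pd <- faith_pd(tab, tree)
  expect_equal(unname(pd["all"]), sum(tree$edge.length))
  expect_equal(unname(pd["onlyA"]), 2)  # tip branch + its parent branch
  expect_equal(unname(pd["none"]), 0)
  # monotone under adding a present tip; matches enumeration oracle
  set.seed(21)
  tr <- simulate_tree(8, seed = 2)
  tab2 <- random_table(n_feat = 8, n_samp = 3, feature_ids = tr$tip.label)
  m2 <- unclass(tab2); m2[2, 1] <- 0L
  tab2 <- feature_table(m2)
  expect_equal(faith_pd(tab2, tr), oracle_faith_pd(tab2, tr),
               tolerance = 1e-12)
  grown <- unclass(tab2)
  grown[2, 1] <- 1L
  expect_true(all(faith_pd(feature_table(grown), tr) >= faith_pd(tab2, tr)))
  # missing tips are named in the error
  bad <- random_table(n_feat = 2, n_samp = 2, feature_ids = c("A", "nope"))
  expect_error(faith_pd(bad, tree), "nope")
})

test_that("Jaccard and Bray-Curtis match their set/abundance formulas", {
  tab <- presence_table(list(x = c("A", "B", "C"), y = c("B", "C", "D"),
                             z = c("A", "B", "C"), w = "E"),
                        c("A", "B", "C", "D", "E"))
  dj <- jaccard(tab)
  expect_equal(dj["x", "y"], 0.5)  # 1 - 2/4
  expect_equal(dj["x", "z"], 0)
  expect_equal(dj["x", "w"], 1)
  m <- matrix(c(2, 0, 0, 2), 2, dimnames = list(c("A", "B"), c("s1", "s2")))
  expect_equal(bray_curtis(feature_table(m))["s1", "s2"], 1)
  set.seed(31)
  for (i in 1:5) {
    tab2 <- random_table(n_feat = 10, n_samp = 5)
    expect_equal(unclass(bray_curtis(tab2)), oracle_bray_curtis(tab2),
                 tolerance = 1e-12)
  }
  # both-empty samples are at distance zero
  m0 <- matrix(c(0, 0, 0, 0, 1, 2), nrow = 2,
               dimnames = list(c("A", "B"), c("e1", "e2", "full")))
  expect_equal(jaccard(feature_table(m0))["e1", "e2"], 0)
  expect_equal(bray_curtis(feature_table(m0))["e1", "e2"], 0)
})

test_that("unweighted UniFrac matches branch enumeration on the reference tree", {
  tree <- balanced_tree()
  tab <- presence_table(list(X = c("A", "B"), Y = c("C", "D"),
                             Z = "A", ZC = c("A", "C")),
                        c("A", "B", "C", "D"))
  d <- unweighted_unifrac(tab, tree)
  expect_equal(d["X", "Y"], 1)    # no shared branches
  expect_equal(d["Z", "ZC"], 0.5) # shared 2 of union 4
  expect_equal(d["X", "X"], 0)
})

test_that("UniFrac family agrees with the per-branch summation oracle on random trees", {
  skip_if_not_installed("phangorn")
  set.seed(41)
  for (i in 1:10) {
    tr <- simulate_tree(8, seed = 100 + i)
    m <- matrix(rpois(8 * 4, 4), 8, 4,
                dimnames = list(tr$tip.label, paste0("s", 1:4)))
    m[, 1] <- m[, 1] + 1L  # guard against all-zero samples
    m[1, ] <- m[1, ] + 1L
    tab <- feature_table(m)
    expect_equal(unclass(unweighted_unifrac(tab, tr)),
                 oracle_unweighted_unifrac(tab, tr), tolerance = 1e-12)
    for (a in c(0, 0.5, 1)) {
      expect_equal(unclass(generalized_unifrac(tab, tr, alpha = a)),
                   oracle_generalized_unifrac(tab, tr, a), tolerance = 1e-12)
    }
    expect_equal(unclass(generalized_unifrac(tab, tr, alpha = 1)),
                 oracle_weighted_normalized_unifrac(tab, tr),
                 tolerance = 1e-12)
  }
})

test_that("generalized UniFrac validates inputs and bounds", {
  tr <- simulate_tree(6, seed = 9)
  tab <- random_table(n_feat = 6, n_samp = 3, feature_ids = tr$tip.label)
  expect_error(generalized_unifrac(tab, tr, alpha = 1.5), "alpha")
  m <- unclass(tab); m[, 1] <- 0L
  expect_error(generalized_unifrac(feature_table(m), tr), "zero total")
  d <- generalized_unifrac(tab, tr, 0.5)
  expect_true(all(d >= 0 & d <= 1))
  # two-tip fully disjoint communities are at distance 1 for any alpha
  two <- ape::read.tree(text = "(A:1,B:1);")
  tab2 <- feature_table(matrix(c(5L, 0L, 0L, 7L), 2,
                               dimnames = list(c("A", "B"), c("x", "y"))))
  for (a in c(0, 0.3, 1)) {
    expect_equal(generalized_unifrac(tab2, two, a)["x", "y"], 1)
  }
})

test_that("PCoA embeds Euclidean configurations exactly", {
  # collinear points 0, 1, 2: one positive eigenvalue
  d <- distance_matrix(matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3,
                              dimnames = list(letters[1:3], letters[1:3])))
  ord <- pcoa(d)
  expect_equal(sum(ord$eigenvalues > 1e-9), 1L)
  expect_equal(as.numeric(dist(ord$coordinates)), c(1, 2, 1), tolerance = 1e-9)
  # random 4x2 point set: distances reconstructed to 1e-9
  set.seed(51)
  pts <- matrix(rnorm(8), 4, 2)
  dm <- as.matrix(dist(pts))
  dimnames(dm) <- list(paste0("p", 1:4), paste0("p", 1:4))
  ord2 <- pcoa(distance_matrix(dm))
  expect_equal(as.matrix(dist(ord2$coordinates)), unname(dm),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(diff(ord2$eigenvalues) <= 1e-9))
  expect_equal(sum(ord2$proportion_explained), 1, tolerance = 1e-12)
  # cross-check against classical scaling in stats
  cmd <- cmdscale(dm, k = 2, eig = TRUE)
  expect_equal(abs(ord2$coordinates), abs(cmd$points), tolerance = 1e-9,
               ignore_attr = TRUE)
  # degenerate all-zero distances
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  ordz <- pcoa(distance_matrix(z))
  expect_equal(ncol(ordz$coordinates), 0L)
  expect_true(all(abs(ordz$eigenvalues) < 1e-12))
  expect_error(pcoa(distance_matrix(matrix(0, 1, 1,
                                           dimnames = list("a", "a")))),
               "at least 2")
})

test_that("PERMANOVA recovers separation, is label- and order-invariant", {
  # two tight, well-separated clusters -> minimal attainable p (cluster
  # size 10 keeps the chance of a permutation recreating the partition,
  # which would tie the observed F, negligible)
  set.seed(61)
  pts <- rbind(matrix(rnorm(20, 0, 0.01), 10),
               matrix(rnorm(20, 10, 0.01), 10))
  dm <- as.matrix(dist(pts))
  ids <- paste0("s", 1:20)
  dimnames(dm) <- list(ids, ids)
  grp <- setNames(rep(c("a", "b"), each = 10), ids)
  res <- permanova(distance_matrix(dm), grp, n_permutations = 199, seed = 1)
  expect_equal(res$p_value, 1 / 200)
  # relabeling groups and permuting sample order leave p unchanged
  grp2 <- setNames(c("water", "host")[as.integer(factor(grp))], ids)
  res2 <- permanova(distance_matrix(dm), grp2, n_permutations = 199, seed = 1)
  expect_equal(res2$p_value, res$p_value)
  perm_ids <- sample(ids)
  res3 <- permanova(distance_matrix(dm[perm_ids, perm_ids]), grp,
                    n_permutations = 199, seed = 1)
  expect_equal(res3$pseudo_F, res$pseudo_F)
  # all-equal distances: every permutation gives the same F, p = 1
  eq <- matrix(1, 6, 6) - diag(6)
  dimnames(eq) <- list(paste0("t", 1:6), paste0("t", 1:6))
  geq <- setNames(rep(c("a", "b"), 3), paste0("t", 1:6))
  expect_equal(permanova(distance_matrix(eq), geq, 99, seed = 2)$p_value, 1)
  expect_error(permanova(distance_matrix(eq),
                         setNames(rep("a", 6), paste0("t", 1:6)), 99),
               "2 groups")
})

test_that("PERMANOVA pseudo-F agrees with vegan's one-way partition", {
  set.seed(71)
  pts <- matrix(rnorm(24), 12, 2)
  dm <- as.matrix(dist(pts))
  ids <- paste0("s", 1:12)
  dimnames(dm) <- list(ids, ids)
  grp <- setNames(rep(c("a", "b", "c"), each = 4), ids)
  mine <- permanova(distance_matrix(dm), grp, n_permutations = 99, seed = 1)
  veg <- vegan::adonis2(as.dist(dm) ~ g,
                        data = data.frame(g = grp), permutations = 99)
  expect_equal(mine$pseudo_F, veg$F[1], tolerance = 1e-10)
})
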