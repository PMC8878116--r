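four_tip_tree <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

test_that("unweighted UniFrac matches the hand-derived cases", {
  tr <- four_tip_tree()
  expect_equal(unweighted_unifrac(tr, c("A", "B"), c("A", "B")), 0)
  expect_equal(unweighted_unifrac(tr, c("A", "B"), c("C", "D")), 1)
  expect_equal(unweighted_unifrac(tr, c("A", "B"), c("A", "C")), 0.6)
  expect_error(unweighted_unifrac(tr, c("A", "Q"), "B"), "missing.*Q")
})

test_that("weighted UniFrac matches the hand-derived cases", {
  tr <- four_tip_tree()
  expect_equal(weighted_unifrac(tr, c(A = 0.5, B = 0.5),
                                c(A = 0.5, B = 0.5)), 0)
  star <- ape::read.tree(text = "(A:1,B:1,C:1);")
  expect_equal(weighted_unifrac(star, c(A = 1), c(B = 1)), 1)
  expect_equal(weighted_unifrac(tr, c(A = 1), c(B = 1)),
               oracle_weighted_unifrac(tr, c(A = 1), c(B = 1)))
  # raw (unnormalized) form equals the plain weighted branch sum
  expect_equal(weighted_unifrac(star, c(A = 1), c(B = 1),
                                normalized = FALSE), 2)
})

test_that("UniFrac agrees with the exhaustive branch-walk oracle", {
  set.seed(60)
  for (i in 1:40) {
    tr <- random_phylo(8)
    tips <- tr$tip.label
    s1 <- sample(tips, sample(1:6, 1))
    s2 <- sample(tips, sample(1:6, 1))
    expect_equal(unweighted_unifrac(tr, s1, s2),
                 oracle_unweighted_unifrac(tr, s1, s2), tolerance = 1e-12)
    a1 <- setNames(runif(length(s1)), s1)
    a2 <- setNames(runif(length(s2)), s2)
    expect_equal(weighted_unifrac(tr, a1, a2),
                 oracle_weighted_unifrac(tr, a1, a2), tolerance = 1e-12)
  }
})

test_that("unweighted UniFrac is metric on presence sets (triangles)", {
  set.seed(61)
  for (i in 1:25) {
    tr <- random_phylo(8)
    sets <- replicate(3, sample(tr$tip.label, sample(1:7, 1)),
                      simplify = FALSE)
    d12 <- unweighted_unifrac(tr, sets[[1]], sets[[2]])
    d13 <- unweighted_unifrac(tr, sets[[1]], sets[[3]])
    d23 <- unweighted_unifrac(tr, sets[[2]], sets[[3]])
    expect_lte(d12, d13 + d23 + 1e-12)
  }
})

test_that("distance matrices are symmetric and match pair operations", {
  ds <- synthesize_dataset(synthetic_config(
    groups = "YN", n_samples_per_group = 5, n_otus = 30,
    depth_mean = 500, n_core = 0, seed = 19))
  for (metric in c("unweighted_unifrac", "weighted_unifrac",
                   "bray_curtis")) {
    d <- distance_matrix(ds$table, metric, tree = ds$tree)
    expect_true(all(d == t(d)))
    expect_true(all(diag(d) == 0))
  }
  d <- distance_matrix(ds$table, "unweighted_unifrac", tree = ds$tree)
  pres <- ds$table$counts > 0
  ids <- otu_ids(ds$table)
  expect_equal(d[1, 3],
               unweighted_unifrac(ds$tree, ids[pres[1, ]], ids[pres[3, ]]))
  dw <- distance_matrix(ds$table, "weighted_unifrac", tree = ds$tree)
  ra <- relative_abundance(ds$table)
  expect_equal(dw[2, 4],
               weighted_unifrac(ds$tree, ra[2, ], ra[4, ]))
  expect_error(distance_matrix(ds$table, "weighted_unifrac"), "tree")
  one <- filter_samples(ds$table, sample_ids(ds$table)[1])
  expect_equal(dim(distance_matrix(one, "bray_curtis")), c(1, 1))
})

test_that("unweighted UniFrac agrees with picante on a shared dataset", {
  skip_if_not_installed("picante")
  ds <- synthesize_dataset(synthetic_config(
    groups = "YN", n_samples_per_group = 4, n_otus = 16,
    depth_mean = 200, n_core = 0, seed = 23))
  d <- distance_matrix(ds$table, "unweighted_unifrac", tree = ds$tree)
  ref <- as.matrix(picante::unifrac(ds$table$counts, ds$tree))
  expect_equal(unclass(d), ref[rownames(d), colnames(d)],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("PCoA embeds Euclidean distances exactly", {
  # collinear points: one positive eigenvalue, distances reproduced
  x <- c(0, 1, 2)
  d <- as.matrix(dist(x))
  p <- pcoa(d)
  expect_equal(sum(p$eigenvalues > 1e-9), 1)
  rec <- as.matrix(dist(p$coordinates))
  expect_lt(max(abs(rec - d)), 1e-9)
  # points in the plane: two axes reproduce all pairwise distances
  set.seed(3)
  xy <- matrix(rnorm(12), 6, 2)
  d2 <- as.matrix(dist(xy))
  p2 <- pcoa(d2)
  rec2 <- as.matrix(dist(p2$coordinates[, 1:2]))
  expect_lt(max(abs(rec2 - d2)), 1e-9)
  expect_lte(sum(p2$proportion), 1 + 1e-12)
  # all-zero distances: all coordinates zero
  z <- matrix(0, 3, 3)
  expect_true(all(pcoa(z)$coordinates == 0))
})

test_that("UPGMA reproduces the hand-worked merge heights", {
  d <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  u <- upgma(d)
  expect_equal(u$height, c(1, 4))
  tr <- ape::read.tree(text = u$newick)
  expect_setequal(tr$tip.label, c("A", "B", "C"))
})

test_that("UPGMA ties break lexicographically and trees are ultrametric", {
  d <- matrix(1, 3, 3, dimnames = list(c("b", "a", "c"), c("b", "a", "c")))
  diag(d) <- 0
  u <- upgma(d)
  # first merge joins the lexicographically first pair {a, b}
  expect_true(grepl("\\(b:0.5,a:0.5\\)|\\(a:0.5,b:0.5\\)", u$newick))
  set.seed(71)
  pts <- matrix(rnorm(16), 8, 2)
  dd <- as.matrix(dist(pts))
  dimnames(dd) <- list(letters[1:8], letters[1:8])
  uu <- upgma(dd)
  tr <- ape::read.tree(text = uu$newick)
  depths <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
  expect_lt(diff(range(depths)), 1e-9)
  expect_true(all(diff(uu$height) >= -1e-12))
  # agrees with hclust average linkage (heights halved) off tie cases
  hc <- hclust(as.dist(dd), method = "average")
  expect_equal(sort(uu$height), sort(hc$height / 2), tolerance = 1e-12)
})

test_that("MRPP reproduces the exhaustive fixture and tie convention", {
  d <- matrix(10, 6, 6)
  d[1:3, 1:3] <- 0; d[4:6, 4:6] <- 0; diag(d) <- 0
  r <- mrpp_test(d, rep(c("g1", "g2"), each = 3))
  expect_equal(r$method, "exhaustive")
  expect_equal(r$n_permutations, 20)
  expect_equal(r$p_value, 0.1)
  expect_equal(r$delta_observed, 0)
  # all points identical: delta_obs = 0 = all permuted deltas, p = 1
  z <- matrix(0, 6, 6)
  expect_equal(mrpp_test(z, rep(c("g1", "g2"), each = 3))$p_value, 1)
  expect_error(mrpp_test(d, c("a", rep("b", 5))), ">= 2 samples")
})

test_that("MRPP delta and A agree with vegan on a random dataset", {
  set.seed(81)
  pts <- matrix(rnorm(24), 12, 2)
  d <- as.matrix(dist(pts))
  grp <- rep(c("u", "v", "w"), each = 4)
  mine <- mrpp_test(d, grp, n_permutations = 499, seed = 1,
                    exhaustive = FALSE)
  ref <- vegan::mrpp(dist(pts), grp, permutations = 499,
                     weight.type = 1)
  expect_equal(mine$delta_observed, ref$delta, tolerance = 1e-12)
  # A is 1 - delta/E(delta); expectations differ only by permutation noise
  expect_equal(mine$A_statistic, ref$A, tolerance = 0.05)
})

test_that("Monte-Carlo MRPP is deterministic under a fixed seed", {
  set.seed(82)
  d <- as.matrix(dist(matrix(rnorm(30), 15, 2)))
  grp <- rep(c("a", "b", "c"), each = 5)
  r1 <- mrpp_test(d, grp, n_permutations = 199, seed = 5,
                  exhaustive = FALSE)
  r2 <- mrpp_test(d, grp, n_permutations = 199, seed = 5,
                  exhaustive = FALSE)
  expect_identical(r1$p_value, r2$p_value)
})

test_that("pairwise MRPP flags exactly the separated pair", {
  set.seed(83)
  a <- matrix(rnorm(10, 0), 5, 2)
  b <- matrix(rnorm(10, 0.2), 5, 2)
  c_ <- matrix(rnorm(10, 30), 5, 2)
  d <- as.matrix(dist(rbind(a, b, c_)))
  grp <- rep(c("a", "b", "c"), each = 5)
  pw <- pairwise_mrpp(d, grp, n_permutations = 499, seed = 2)
  expect_equal(nrow(pw), 3)  # C(3, 2)
  expect_true(pw$significant[pw$group1 == "a" & pw$group2 == "c"])
  expect_true(pw$significant[pw$group1 == "b" & pw$group2 == "c"])
  expect_false(pw$significant[pw$group1 == "a" & pw$group2 == "b"])
  pw_adj <- pairwise_mrpp(d, grp, n_permutations = 499, seed = 2,
                          p_adjust = "BH")
  expect_true(all(pw_adj$p_value >= pw$p_value - 1e-12))
})
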