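test_that("unweighted UniFrac matches hand-computable cases", {
  tree <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(unweighted_unifrac(c("A", "B"), c("A", "B"), tree), 0.0)
  expect_equal(unweighted_unifrac(c("A", "B"), c("C", "D"), tree), 1.0)
  expect_error(unweighted_unifrac(character(0), character(0), tree), "empty")
  expect_error(unweighted_unifrac("Z", "A", tree), "absent")
})

test_that("weighted UniFrac matches hand-computable cases", {
  tree <- parse_newick("(A:1,B:1);")
  expect_equal(weighted_unifrac(c(A = 1), c(B = 1), tree), 2.0)
  expect_equal(weighted_unifrac(c(A = 0.5, B = 0.5), c(A = 0.5, B = 0.5),
                                tree), 0.0)
  expect_error(weighted_unifrac(c(Z = 1), c(A = 1), tree), "absent")
  # normalized form divides by the maximum attainable value
  expect_equal(weighted_unifrac(c(A = 1), c(B = 1), tree, normalized = TRUE),
               1.0)
})

test_that("both UniFrac kinds match the exhaustive branch-walk oracle", {
  for (s in 1:40) {
    cs <- random_unifrac_case(s)
    expect_equal(unweighted_unifrac(cs$a, cs$b, cs$tree),
                 oracle_unweighted_unifrac(cs$a, cs$b, cs$tree),
                 tolerance = 1e-12)
    expect_equal(weighted_unifrac(cs$wa, cs$wb, cs$tree),
                 oracle_weighted_unifrac(cs$wa, cs$wb, cs$tree),
                 tolerance = 1e-12)
  }
})

test_that("UniFrac agrees with phyloseq on a shared fixture", {
  skip_if_not_installed("phyloseq")
  set.seed(14)
  tree <- ape::rtree(12)
  counts <- matrix(rpois(4 * 12, 20), 4, 12,
                   dimnames = list(paste0("s", 1:4), tree$tip.label))
  storage.mode(counts) <- "integer"
  du <- unifrac_matrix(counts, tree, "unweighted", rarefy = FALSE)
  dw <- unifrac_matrix(counts, tree, "weighted", rarefy = FALSE)
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(counts, taxa_are_rows = FALSE),
    phyloseq::phy_tree(tree)
  )
  ref_u <- phyloseq::UniFrac(ps, weighted = FALSE)
  ref_w <- phyloseq::UniFrac(ps, weighted = TRUE, normalized = FALSE)
  expect_equal(as.matrix(du), as.matrix(ref_u), tolerance = 1e-10)
  expect_equal(as.matrix(dw), as.matrix(ref_w), tolerance = 1e-10)
})

test_that("weighted UniFrac is invariant to branch subdivision", {
  set.seed(15)
  tree <- ape::rtree(8)
  wa <- setNames(rgamma(8, 1), tree$tip.label)
  wb <- setNames(rgamma(8, 1), tree$tip.label)
  wa <- wa / sum(wa)
  wb <- wb / sum(wb)
  base <- weighted_unifrac(wa, wb, tree)
  for (e in sample(nrow(tree$edge), 3)) {
    split_tree <- subdivide_edge(tree, e)
    expect_equal(weighted_unifrac(wa, wb, split_tree), base,
                 tolerance = 1e-12)
  }
})

test_that("unifrac_matrix is symmetric, deterministic, and zero for duplicates", {
  set.seed(16)
  tree <- ape::rtree(20)
  base <- c(rmultinom(1, 4000, rep(1, 20)))
  counts <- rbind(a = base, b = base,
                  c = c(rmultinom(1, 4000, runif(20))))
  colnames(counts) <- tree$tip.label
  storage.mode(counts) <- "integer"
  for (kind in c("weighted", "unweighted")) {
    d1 <- unifrac_matrix(counts, tree, kind, depth = 4000, seed = 2)
    d2 <- unifrac_matrix(counts, tree, kind, depth = 4000, seed = 2)
    expect_identical(d1, d2)
    m <- as.matrix(d1)
    expect_equal(m, t(m), tolerance = 1e-12)
    expect_true(all(diag(m) == 0))
    expect_true(all(m >= 0))
    # duplicated rows at full depth rarefy to the same vector
    expect_equal(m["a", "b"], 0)
  }
  du <- as.matrix(unifrac_matrix(counts, tree, "unweighted", depth = 4000,
                                 seed = 2))
  expect_true(all(du <= 1 + 1e-12))
})

test_that("shallow samples are excluded from the distance matrix", {
  set.seed(17)
  tree <- ape::rtree(10)
  counts <- rbind(ok1 = c(rmultinom(1, 2000, rep(1, 10))),
                  ok2 = c(rmultinom(1, 2500, rep(1, 10))),
                  thin = c(rmultinom(1, 300, rep(1, 10))))
  colnames(counts) <- tree$tip.label
  storage.mode(counts) <- "integer"
  expect_warning(
    unifrac_matrix(counts, tree, "weighted", depth = 1000, seed = 1),
    "excluded"
  )
  d <- suppressWarnings(
    unifrac_matrix(counts, tree, "weighted", depth = 1000, seed = 1)
  )
  expect_setequal(attr(d, "Labels"), c("ok1", "ok2"))
  expect_equal(attr(d, "excluded"), "thin")
})

test_that("PCoA recovers known configurations", {
  # collinear points at 0, 1, 3: one positive axis carries everything
  d <- dist(c(0, 1, 3))
  expect_warning(pcoa(d, n_axes = 2), "positive eigenvalues")
  res <- suppressWarnings(pcoa(d, n_axes = 2))
  expect_equal(res$proportion_explained[1], 1.0, tolerance = 1e-9)
  expect_equal(ncol(res$coordinates), 1)  # only one positive eigenvalue
  # planar configuration: all positive axes reconstruct the distances
  set.seed(18)
  pts <- matrix(rnorm(10), 5, 2)
  d2 <- dist(pts)
  res2 <- pcoa(d2, n_axes = Inf)
  expect_equal(sum(res2$eigenvalues > max(res2$eigenvalues) * 1e-9), 2)
  recon <- dist(res2$coordinates)
  expect_equal(as.numeric(recon), as.numeric(d2), tolerance = 1e-9)
  # identical points: no positive eigenvalues, empty coordinates
  d3 <- dist(rep(0, 4))
  res3 <- suppressWarnings(pcoa(d3, n_axes = 3))
  expect_equal(ncol(res3$coordinates), 0)
  expect_true(all(abs(res3$eigenvalues) < 1e-12))
})

test_that("PCoA axis orientation is deterministic", {
  set.seed(19)
  pts <- matrix(rnorm(16), 8, 2)
  res <- pcoa(dist(pts), n_axes = 2)
  for (j in 1:2) {
    expect_gt(res$coordinates[which.max(abs(res$coordinates[, j])), j], 0)
  }
})

test_that("distance R2 decomposes sums of squares exactly", {
  # groups of identical points: within-group SS is zero, R2 = 1
  pts <- c(0, 0, 5, 5)
  r <- dist_r2(dist(pts), c("g1", "g1", "g2", "g2"))
  expect_equal(r$r2, 1.0)
  expect_equal(r$ss_within, 0)
  # symmetric 4-point crosswise grouping, by hand:
  # d(1,2)=1 within g1, d(3,4)=1 within g2, cross distances sqrt(2), 1, ...
  pts2 <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1), 4, 2, byrow = TRUE)
  grp <- c("a", "a", "b", "b")
  r2 <- dist_r2(dist(pts2), grp)
  oracle <- oracle_dist_r2(dist(pts2), grp)
  expect_equal(r2$ss_total, oracle$ss_total, tolerance = 1e-12)
  expect_equal(r2$ss_within, oracle$ss_within, tolerance = 1e-12)
  expect_equal(r2$r2, oracle$r2, tolerance = 1e-12)
  # random configurations: decomposition matches the loop oracle
  set.seed(20)
  for (i in 1:10) {
    n <- 60
    conf <- matrix(rnorm(n * 3), n, 3)
    labels <- sample(letters[1:4], n, replace = TRUE)
    d <- dist(conf)
    ours <- dist_r2(d, labels)
    orc <- oracle_dist_r2(d, labels)
    expect_equal(ours$r2, orc$r2, tolerance = 1e-12)
    expect_equal(ours$ss_between + ours$ss_within, ours$ss_total,
                 tolerance = 1e-9)
    expect_true(ours$r2 >= 0 && ours$r2 <= 1)
  }
  expect_error(dist_r2(dist(pts), rep("g", 4)), "2 groups")
})

test_that("distance R2 agrees with vegan's PERMANOVA decomposition", {
  set.seed(21)
  conf <- matrix(rnorm(30 * 2), 30, 2)
  grp <- factor(sample(c("x", "y", "z"), 30, replace = TRUE))
  d <- dist(conf)
  ours <- dist_r2(d, as.character(grp))
  ref <- vegan::adonis2(d ~ grp, permutations = 2)
  expect_equal(ours$r2, ref$R2[1], tolerance = 1e-10)
})
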