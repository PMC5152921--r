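# row normalization, Manhattan distances, complete linkage, tree queries,
# Newick export

test_that("row normalization: z-score, minmax, constant-row guard, idempotence", {
  m <- matrix(c(1, 2, 3,
                5, 5, 5), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "b"), c("x", "y", "z")))
  z <- row_normalize(m, "zscore")
  expect_equal(unname(z["a", ]), c(-1, 0, 1))
  expect_equal(unname(z["b", ]), c(0, 0, 0))
  expect_equal(row_normalize(z, "zscore"), z)  # idempotent
  mm <- row_normalize(m, "minmax")
  expect_equal(unname(mm["a", ]), c(0, 0.5, 1))
  expect_equal(unname(mm["b", ]), c(0, 0, 0))
  expect_equal(row_normalize(m, "none"), m)
  expect_error(row_normalize(matrix(1, 2, 1)), ">= 2")
})

test_that("species distance is columnwise Manhattan", {
  m <- matrix(c(1, 4,
                2, 6), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(as.numeric(species_distance(m)), 7)  # |3| + |4|
  same <- cbind(x = c(1, 2), y = c(1, 2))
  rownames(same) <- c("a", "b")
  expect_equal(as.numeric(species_distance(same)), 0)
  # metric properties against brute-force pairwise sums
  set.seed(7)
  for (rep in 1:10) {
    v <- matrix(rnorm(5 * 6), 5, 6,
                dimnames = list(paste0("a", 1:5), paste0("s", 1:6)))
    D <- as.matrix(species_distance(v))
    brute <- outer(1:6, 1:6, Vectorize(function(i, j)
      sum(abs(v[, i] - v[, j]))))
    expect_equal(unname(D), brute)
    expect_equal(D, t(D))
    for (i in 1:6) for (j in 1:6) for (k in 1:6)
      expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
  }
})

test_that("hand-worked 3-leaf complete linkage", {
  tr <- complete_linkage(toy3_dist())
  expect_equal(tr$height, c(1, 5))
  expect_setequal(cut_partition(tr, 2),
                  list(c("A", "B"), "C"))
  expect_equal(cut_partition(tr, 1), list(c("A", "B", "C")))
  expect_setequal(cut_partition(tr, 3), list("A", "B", "C"))
  expect_error(cut_partition(tr, 0), "between 1 and")
  expect_error(cut_partition(tr, 4), "between 1 and")
})

test_that("equal-distance ties merge lowest (row, column) pair first", {
  D <- matrix(1, 4, 4, dimnames = list(paste0("L", 1:4), paste0("L", 1:4)))
  diag(D) <- 0
  tr <- complete_linkage(D)
  expect_equal(tr$height, c(1, 1, 1))
  # declared order: (L1,L2) first, then (L3,L4), then the two clusters
  sets <- hclust_merge_sets(tr)
  expect_equal(sets[[1]], c(1L, 2L))
  expect_equal(sets[[2]], c(3L, 4L))
  expect_equal(sets[[3]], 1:4)
  expect_error(complete_linkage(matrix(0, 1, 1)), "at least 2 leaves")
})

test_that("linkage agrees with the naive O(n^3) agglomeration oracle", {
  set.seed(31)
  for (rep in 1:60) {
    n <- sample(6:10, 1)
    D <- random_dist_matrix(n, ties = rep %% 3 == 0)
    tr <- complete_linkage(D)
    oracle <- naive_complete_linkage(D)
    expect_equal(tr$height, oracle$heights)
    expect_equal(hclust_merge_sets(tr), oracle$sets)
  }
})

test_that("linkage agrees with stats::hclust on tie-free matrices", {
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(5:9, 1)
    D <- random_dist_matrix(n)
    mine <- complete_linkage(D)
    ref <- stats::hclust(stats::as.dist(D), method = "complete")
    expect_equal(stats::cophenetic(mine), stats::cophenetic(ref))
  }
})

test_that("merge heights equal the within-cluster diameter (complete-linkage invariant)", {
  set.seed(17)
  D <- random_dist_matrix(8)
  tr <- complete_linkage(D)
  for (s in seq_along(tr$height)) {
    members <- hclust_merge_sets(tr)[[s]]
    expect_equal(tr$height[s], max(D[members, members]))
  }
  # heights are non-decreasing (ultrametric property)
  expect_true(all(diff(tr$height) >= 0))
})

test_that("clustering is invariant to assay-row and species-column order", {
  sim <- simulate_assay_matrix(default_species_groups(), seed = 3)
  m <- row_normalize(sim$matrix)
  tr1 <- complete_linkage(species_distance(m))
  set.seed(5)
  perm_rows <- sample(nrow(m$values))
  perm_cols <- sample(ncol(m$values))
  v2 <- m$values[perm_rows, perm_cols]
  tr2 <- complete_linkage(species_distance(v2))
  c1 <- as.matrix(stats::cophenetic(tr1))
  c2 <- as.matrix(stats::cophenetic(tr2))
  expect_equal(c2[rownames(c1), colnames(c1)], c1)
})

test_that("is_clade recognises exactly the descendant sets", {
  tr <- complete_linkage(toy3_dist())
  expect_true(is_clade(tr, c("A", "B", "C")))  # root
  expect_true(is_clade(tr, "B"))               # singleton
  expect_true(is_clade(tr, c("A", "B")))
  expect_false(is_clade(tr, c("A", "C")))
  expect_false(is_clade(tr, c("B", "C")))
  expect_error(is_clade(tr, c("A", "Z")), "unknown leaf")
})

test_that("Newick export follows the half-height convention and round-trips", {
  tr <- complete_linkage(toy3_dist())
  phy <- ape::read.tree(text = to_newick(tr))
  expect_setequal(phy$tip.label, c("A", "B", "C"))
  # ((A:0.5,B:0.5):2.0,C:2.5); -- leaves at depth 2.5 = root height 5 / 2
  depths <- ape::node.depth.edgelength(phy)[1:3]
  expect_equal(unname(depths), rep(2.5, 3))
  ab <- phy$edge.length[phy$edge[, 2] %in%
                          match(c("A", "B"), phy$tip.label)]
  expect_equal(ab, c(0.5, 0.5))
  # two-leaf tree: (A:h, B:h);
  D2 <- matrix(c(0, 3, 3, 0), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  phy2 <- ape::read.tree(text = to_newick(complete_linkage(D2)))
  expect_equal(sort(phy2$edge.length), c(1.5, 1.5))
})

test_that("Newick file round-trip preserves clade structure for all subsets", {
  set.seed(23)
  D <- random_dist_matrix(5)
  tr <- complete_linkage(D)
  f <- withr::local_tempfile(fileext = ".nwk")
  to_newick(tr, f)
  phy <- from_newick(f)
  leaves <- tr$labels
  subsets <- unlist(lapply(2:4, function(k)
    utils::combn(leaves, k, simplify = FALSE)), recursive = FALSE)
  for (s in subsets)
    expect_identical(ape::is.monophyletic(phy, s), is_clade(tr, s))
})
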