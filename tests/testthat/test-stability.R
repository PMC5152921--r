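# bootstrap recapitulation and coregulator importance

test_that("cluster_pattern validates disjointness and coverage", {
  expect_error(cluster_pattern(list(c("a", "b"))), ">= 2")
  expect_error(cluster_pattern(list(c("a", "b"), c("b", "c"))), "disjoint")
  expect_error(cluster_pattern(list(A = "a", B = "b"),
                               subclusters = list(c("a", "z"))),
               "not in partition")
  p <- cluster_pattern(list(c("a", "b"), c("c")))
  expect_named(p$partition, c("C1", "C2"))
})

test_that("recapitulation_check is self-consistent on the reference tree", {
  sim <- simulate_assay_matrix(default_species_groups(), seed = 2)
  m <- row_normalize(sim$matrix)
  tree <- complete_linkage(species_distance(m))
  pattern <- cluster_pattern(cut_partition(tree, 2))
  ch <- recapitulation_check(tree, pattern)
  expect_true(ch$partition_match)
  expect_true(all(ch$subclusters))
  # swapping members across groups breaks the match
  part <- pattern$partition
  swapped <- list(c(part[[1]][-1], part[[2]][1]),
                  c(part[[2]][-1], part[[1]][1]))
  ch2 <- recapitulation_check(tree, cluster_pattern(swapped))
  expect_false(ch2$partition_match)
  expect_error(
    recapitulation_check(tree, cluster_pattern(list("x", "y"))),
    "do not match")
})

test_that("a k=2 partition match implies both groups are clades", {
  set.seed(41)
  for (rep in 1:25) {
    v <- matrix(rnorm(4 * 6), 4, 6,
                dimnames = list(paste0("a", 1:4), paste0("s", 1:6)))
    tree <- complete_linkage(species_distance(v))
    pattern <- cluster_pattern(cut_partition(tree, 2))
    ch <- recapitulation_check(tree, pattern)
    if (ch$partition_match) expect_true(all(ch$subclusters))
  }
})

test_that("exactly duplicated group columns give recapitulation 1 in any mode", {
  # zero noise, effect present: species within a group are identical, so
  # no row resample can break the split
  sim <- simulate_assay_matrix(default_species_groups(), noise_sd = 0,
                               effect_size = 3, seed = 1)
  m <- sim$matrix
  pattern <- cluster_pattern(sim$truth$true_partition)
  for (mode in c("plain", "stratified")) {
    r <- bootstrap_recapitulation(m, pattern, B = 60, seed = 2, mode = mode)
    expect_equal(r$overall_recapitulation, 1)
    expect_equal(unname(r$subcluster_recapitulation), c(1, 1))
  }
})

test_that("plain-mode rate matches the exhaustive enumeration oracle", {
  mat <- toy_boot_matrix()
  pattern <- toy_boot_pattern()
  p_exact <- enum_recap_prob(mat, pattern)   # all 3^3 ordered resamples
  expect_gt(p_exact, 0)
  expect_lt(p_exact, 1)
  B <- 2000
  r <- bootstrap_recapitulation(mat, pattern, B = B, seed = 11,
                                mode = "plain")
  mc_se <- sqrt(p_exact * (1 - p_exact) / B)
  expect_lt(abs(r$overall_recapitulation - p_exact), 3 * mc_se)
})

test_that("stability reports are deterministic in (matrix, pattern, B, seed, mode)", {
  sim <- simulate_assay_matrix(default_species_groups(), seed = 4)
  m <- row_normalize(sim$matrix)
  pattern <- cluster_pattern(sim$truth$true_partition)
  r1 <- bootstrap_recapitulation(m, pattern, B = 150, seed = 8)
  r2 <- bootstrap_recapitulation(m, pattern, B = 150, seed = 8)
  expect_identical(r1, r2)
  i1 <- coregulator_importance(m, pattern, B = 80, seed = 8)
  i2 <- coregulator_importance(m, pattern, B = 80, seed = 8)
  expect_identical(i1, i2)
})

test_that("rates are invariant to species-column order under matched seeds", {
  sim <- simulate_assay_matrix(default_species_groups(), seed = 6)
  m <- row_normalize(sim$matrix)
  pattern <- cluster_pattern(sim$truth$true_partition)
  r1 <- bootstrap_recapitulation(m, pattern, B = 100, seed = 3)
  set.seed(1)
  perm <- sample(ncol(m$values))
  m2 <- assay_matrix(m$values[, perm], m$annotations)
  r2 <- bootstrap_recapitulation(m2, pattern, B = 100, seed = 3)
  expect_equal(r1$overall_recapitulation, r2$overall_recapitulation)
  expect_equal(r1$subcluster_recapitulation, r2$subcluster_recapitulation)
})

test_that("importance is bounded, zero-flagged for absent coregulators", {
  sim <- simulate_assay_matrix(default_species_groups(), seed = 5)
  m <- row_normalize(sim$matrix)
  pattern <- cluster_pattern(sim$truth$true_partition)
  # restrict to assays without ACTR so the flag is vacuously absent
  keep <- which(!m$annotations$ACTR)
  sub <- assay_matrix(m$values[keep, ], m$annotations[keep, ])
  expect_warning(
    imp <- coregulator_importance(sub, pattern, B = 50, seed = 1),
    "absent from every assay")
  expect_identical(unname(imp$importance["ACTR"]), 0)
  expect_true(imp$vacuous[["ACTR"]])
  expect_true(all(imp$importance >= -1 & imp$importance <= 1))
})

test_that("removing a coregulator that covers nearly all assays errors", {
  layout <- default_assay_layout()[c(2, 9, 10), ]  # RXR_WT in 2 of 3 rows
  v <- matrix(rnorm(3 * 4), 3, 4,
              dimnames = list(layout$assay, paste0("s", 1:4)))
  m <- assay_matrix(v, layout)
  pattern <- cluster_pattern(list(c("s1", "s2"), c("s3", "s4")))
  expect_error(coregulator_importance(m, pattern, B = 10, seed = 1,
                                      coregulators = "RXR_WT"),
               "fewer than 2 rows")
})

test_that("planted drivers rank above non-drivers", {
  hits <- vapply(1:5, function(s) {
    sim <- simulate_assay_matrix(default_species_groups(), seed = s)
    m <- row_normalize(sim$matrix)
    pattern <- cluster_pattern(sim$truth$true_partition)
    imp <- coregulator_importance(m, pattern, B = 100, seed = s)
    top2 <- names(sort(imp$importance, decreasing = TRUE))[1:2]
    setequal(top2, c("SRC1", "RXR_WT"))
  }, logical(1))
  expect_true(all(hits))
})
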