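# Independent oracles and shared fixtures for the test suite.

# Naive O(n^3) complete-linkage agglomeration: cluster distances are
# recomputed from scratch at every step as the maximum leaf-pair distance
# taken from the ORIGINAL distance matrix (no Lance-Williams update), with
# the same declared tie rule (lowest row index, then column index, over
# clusters in creation order).  Returns merge heights and the leaf-index
# set created by each merge.
naive_complete_linkage <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))  # creation order: leaves first
  heights <- numeric(n - 1)
  sets <- vector("list", n - 1)
  for (s in seq_len(n - 1)) {
    m <- length(clusters)
    best <- Inf; bi <- 0L; bj <- 0L
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        dij <- max(D[clusters[[i]], clusters[[j]]])
        if (dij < best) { best <- dij; bi <- i; bj <- j }
      }
    }
    heights[s] <- best
    merged <- sort(c(clusters[[bi]], clusters[[bj]]))
    sets[[s]] <- merged
    clusters <- c(clusters[-c(bi, bj)], list(merged))
  }
  list(heights = heights, sets = sets)
}

# leaf-index sets created by each merge of an hclust object
hclust_merge_sets <- function(tree) {
  m <- tree$merge
  sets <- vector("list", nrow(m))
  for (s in seq_len(nrow(m))) {
    get <- function(code) if (code < 0) -code else sets[[code]]
    sets[[s]] <- sort(c(get(m[s, 1]), get(m[s, 2])))
  }
  sets
}

# Exact recapitulation probability by exhaustive enumeration of all
# ordered row-resamples (n^n equally likely draws), scored through the
# public single-tree path (complete_linkage + recapitulation_check) --
# independent of the bootstrap's internal mask path.
enum_recap_prob <- function(mat, pattern) {
  nr <- nrow(mat$values)
  combos <- as.matrix(expand.grid(rep(list(seq_len(nr)), nr)))
  hits <- apply(combos, 1, function(idx) {
    vals <- mat$values[idx, , drop = FALSE]
    rownames(vals) <- paste0("r", seq_len(nr))
    tree <- complete_linkage(species_distance(vals))
    ch <- recapitulation_check(tree, pattern)
    ch$partition_match && all(ch$subclusters)
  })
  mean(hits)
}

# 3-leaf worked example: d(A,B)=1, d(A,C)=5, d(B,C)=4
toy3_dist <- function() {
  matrix(c(0, 1, 5,
           1, 0, 4,
           5, 4, 0), 3, 3,
         dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
}

# Small deterministic assay matrix over 4 species in two groups; rows 1-2
# support the planted split {s1,s2} | {s3,s4}, row 3 conflicts with it, so
# the resampling recapitulation probability is strictly between 0 and 1.
toy_boot_matrix <- function(n_conflict = 1) {
  support <- rbind(c(0, 0.1, 3.0, 3.2),
                   c(0.05, 0, 3.1, 3.0))
  conflict <- matrix(rep(c(0, 2.9, 0.2, 3.1), n_conflict),
                     nrow = n_conflict, byrow = TRUE)
  values <- rbind(support, conflict)
  dimnames(values) <- list(paste0("a", seq_len(nrow(values))),
                           c("s1", "s2", "s3", "s4"))
  ann <- data.frame(assay = rownames(values), assay_class = "TT",
                    ligand = "LCA", RXR_WT = FALSE, RXR_AF2 = FALSE,
                    SRC1 = c(rep(TRUE, 2), rep(FALSE, n_conflict)),
                    GRIP1 = FALSE, ACTR = FALSE)
  assay_matrix(values, ann)
}

toy_boot_pattern <- function() {
  cluster_pattern(list(G1 = c("s1", "s2"), G2 = c("s3", "s4")))
}

# random symmetric distance matrix with zero diagonal; `ties = TRUE`
# rounds to small integers so minimal pairs collide and the declared
# tie-breaking rule is exercised
random_dist_matrix <- function(n, ties = FALSE) {
  x <- matrix(stats::runif(n * n, 1, 10), n, n)
  D <- (x + t(x)) / 2
  if (ties) D <- round(D)
  diag(D) <- 0
  dimnames(D) <- list(paste0("L", seq_len(n)), paste0("L", seq_len(n)))
  D
}
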