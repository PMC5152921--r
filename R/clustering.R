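#' Row-normalize an assay matrix
#'
#' Normalizes each assay (row) across species to remove magnitudinal
#' response differences between assays before clustering.  `zscore`
#' centres each row to mean 0 and scales to unit sample standard deviation
#' (n - 1 denominator); `minmax` maps each row onto \[0, 1\].  Constant
#' rows carry no contrast and are mapped to all-zeros under either method.
#'
#' @param x An [assay_matrix()] or a plain numeric matrix with >= 2
#'   columns.
#' @param method `"zscore"` (default), `"minmax"`, or `"none"`.
#' @return Object of the same type as `x` with normalized rows.
#' @examples
#' row_normalize(matrix(1:3, 1, 3, dimnames = list("a", c("x", "y", "z"))))
#' @export
row_normalize <- function(x, method = c("zscore", "minmax", "none")) {
  method <- match.arg(method)
  values <- if (inherits(x, "assay_matrix")) x$values else x
  if (ncol(values) < 2)
    stop("row normalization needs >= 2 values (species) per row")
  out <- switch(method,
    none = values,
    zscore = t(apply(values, 1, function(v) {
      s <- stats::sd(v)
      if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
    })),
    minmax = t(apply(values, 1, function(v) {
      r <- diff(range(v))
      if (r == 0) rep(0, length(v)) else (v - min(v)) / r
    })))
  dimnames(out) <- dimnames(values)
  if (inherits(x, "assay_matrix")) assay_matrix(out, x$annotations) else out
}

#' Manhattan distance between species profiles
#'
#' Pairwise L1 distance between species (columns) across all assays
#' (rows) of a -- typically row-normalized -- assay matrix.
#'
#' @param x An [assay_matrix()] or numeric matrix (assays x species).
#' @return A [stats::dist] object over species.
#' @export
species_distance <- function(x) {
  values <- if (inherits(x, "assay_matrix")) x$values else x
  stats::dist(t(values), method = "manhattan")
}

# Agglomerative complete-linkage core.
#
# Active clusters are kept in creation order: input leaves 1..n first, new
# clusters appended as they form.  At each step the minimal entry of the
# active distance matrix is merged; ties are broken by the lowest (row,
# column) index pair in that ordering -- the package's determinism
# contract.  Inter-cluster distance is the maximum pairwise member
# distance (Lance-Williams max update).  Leaf memberships are tracked as
# bitmasks (sum of 2^(leaf-1), exact for <= 52 leaves) so partition and
# clade checks in the bootstrap loop are integer comparisons.
#
# Returns merge codes (hclust convention: negative = leaf, positive =
# earlier merge), merge heights, per-merge leaf bitmasks, and the active
# bitmasks at the step where `k_snapshot` clusters remained.
.cl_core <- function(D, k_snapshot = NA_integer_) {
  n <- nrow(D)
  if (n < 2) stop("need at least 2 leaves to cluster")
  if (n > 52) stop("bitmask clustering core supports at most 52 leaves")
  codes <- -seq_len(n)
  masks <- 2^(seq_len(n) - 1)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  mmasks <- numeric(n - 1L)
  snapshot <- if (!is.na(k_snapshot) && k_snapshot == n) masks else NULL
  d <- D
  for (s in seq_len(n - 1L)) {
    m <- length(codes)
    dv <- d
    dv[lower.tri(dv, diag = TRUE)] <- Inf
    best <- min(dv)
    cand <- which(dv == best, arr.ind = TRUE)
    pick <- order(cand[, 1L], cand[, 2L])[1L]
    i <- cand[pick, 1L]
    j <- cand[pick, 2L]
    height[s] <- best
    merge[s, ] <- c(codes[i], codes[j])
    newmask <- masks[i] + masks[j]
    mmasks[s] <- newmask
    newd <- pmax(d[i, ], d[j, ])
    keep <- seq_len(m)[-c(i, j)]
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    codes <- c(codes[keep], s)
    masks <- c(masks[keep], newmask)
    if (!is.na(k_snapshot) && m - 1L == k_snapshot) snapshot <- masks
  }
  list(merge = merge, height = height, mmasks = mmasks,
       snapshot = snapshot)
}

#' Complete-linkage hierarchical clustering with a declared tie rule
#'
#' Agglomerative clustering where the distance between two clusters is the
#' maximum pairwise distance between their members.  Ties are resolved
#' deterministically: among all minimal-distance pairs, the pair with the
#' lowest (row index, column index) in the current cluster ordering
#' (input leaves first, newly formed clusters appended) merges first.
#'
#' @param d A [stats::dist] object or symmetric numeric distance matrix.
#' @param labels Leaf labels; defaults to those carried by `d`.
#' @return An object of class [stats::hclust] (usable with
#'   [stats::cutree()], [stats::cophenetic()], plotting, and
#'   [to_newick()]).
#' @examples
#' d <- matrix(c(0, 1, 5, 1, 0, 4, 5, 4, 0), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' complete_linkage(d)$height  # 1, 5
#' @export
complete_linkage <- function(d, labels = NULL) {
  D <- as.matrix(d)
  if (nrow(D) != ncol(D)) stop("`d` must be a square distance matrix")
  if (is.null(labels)) {
    labels <- rownames(D)
    if (is.null(labels)) labels <- paste0("L", seq_len(nrow(D)))
  }
  core <- .cl_core(D)
  merge <- core$merge
  # canonicalise rows the way stats::hclust does: singletons before
  # merges, each in increasing order of |code|
  for (s in seq_len(nrow(merge))) {
    a <- merge[s, 1L]
    b <- merge[s, 2L]
    swap <- (a > 0 && b < 0) || (a < 0 && b < 0 && -a > -b) ||
      (a > 0 && b > 0 && a > b)
    if (swap) merge[s, ] <- c(b, a)
  }
  ord <- function(code) {
    if (code < 0) -code else c(ord(merge[code, 1L]), ord(merge[code, 2L]))
  }
  structure(list(merge = merge, height = core$height,
                 order = ord(nrow(merge)), labels = labels,
                 method = "complete",
                 dist.method = if (inherits(d, "dist"))
                   attr(d, "method") else "user",
                 call = match.call()),
            class = "hclust")
}

#' Cut a dendrogram into k clusters
#'
#' Returns the partition obtained by removing the k - 1 highest merges of
#' the tree (equivalently, [stats::cutree] at `k` for the monotone trees
#' produced by complete linkage).
#'
#' @param tree An [stats::hclust] object.
#' @param k Number of clusters, `1 <= k <=` number of leaves.
#' @return Unnamed list of `k` character vectors (leaf sets).
#' @export
cut_partition <- function(tree, k) {
  n <- length(tree$labels)
  if (k < 1 || k > n) stop("`k` must be between 1 and ", n)
  assign <- stats::cutree(tree, k = k)
  unname(split(tree$labels, assign[tree$labels]))
}

#' Is a leaf set a clade of the tree?
#'
#' `TRUE` iff some node's descendant leaf set equals `leafset` exactly.
#' Singletons and the full leaf set are clades by convention (leaves and
#' root).
#'
#' @param tree An [stats::hclust] object.
#' @param leafset Character vector of leaf names.
#' @return Logical flag.
#' @export
is_clade <- function(tree, leafset) {
  unknown <- setdiff(leafset, tree$labels)
  if (length(unknown))
    stop("unknown leaf name: ", paste(unknown, collapse = ", "))
  target <- sort(unique(leafset))
  if (length(target) <= 1 || length(target) == length(tree$labels))
    return(TRUE)
  sets <- merge_leafsets(tree)
  any(vapply(sets, function(s) identical(sort(s), target), logical(1)))
}

# leaf-name sets of every internal node of an hclust tree
merge_leafsets <- function(tree) {
  m <- tree$merge
  sets <- vector("list", nrow(m))
  for (s in seq_len(nrow(m))) {
    get <- function(code) {
      if (code < 0) tree$labels[-code] else sets[[code]]
    }
    sets[[s]] <- c(get(m[s, 1L]), get(m[s, 2L]))
  }
  sets
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths follow the ultrametric half-height convention of
#' [ape::as.phylo.hclust()]: every node sits at half its merge height, so
#' a branch length is the half-height difference between a node and its
#' parent and all leaves are equidistant from the root.
#'
#' @param tree An [stats::hclust] object.
#' @param file Optional path; when given the string (with a comment header
#'   stating the branch-length convention) is written there.
#' @return The Newick string, invisibly when `file` is given.
#' @export
to_newick <- function(tree, file = NULL) {
  phy <- ape::as.phylo(tree)
  txt <- ape::write.tree(phy)
  if (!is.null(file)) {
    writeLines(c("[branch lengths: ultrametric half merge heights]", txt),
               file)
    return(invisible(txt))
  }
  txt
}

#' Read a Newick dendrogram written by [to_newick()]
#'
#' @param file Path of the Newick file.
#' @return An [ape::read.tree] phylo object.
#' @export
from_newick <- function(file) {
  lines <- readLines(file)
  lines <- lines[!startsWith(lines, "[")]
  ape::read.tree(text = paste(lines, collapse = "\n"))
}
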