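#' Define the reference cluster pattern
#'
#' A cluster pattern is the object the bootstrap tries to recapitulate: a
#' reference partition of the species (the k-cluster cut of the original
#' tree) plus named subclusters whose clade status is scored per draw.
#'
#' @param partition List of >= 2 disjoint character vectors jointly
#'   covering the species; names (e.g. `C1`, `C2`) are kept for
#'   reporting.
#' @param subclusters Named list of character vectors to test as clades;
#'   defaults to the partition groups themselves.
#' @return Object of class `cluster_pattern`.
#' @examples
#' cluster_pattern(default_species_groups())
#' @export
cluster_pattern <- function(partition, subclusters = partition) {
  if (!is.list(partition) || length(partition) < 2)
    stop("`partition` must be a list of >= 2 species sets")
  species <- unlist(partition, use.names = FALSE)
  if (anyDuplicated(species))
    stop("partition sets must be disjoint; duplicated: ",
         paste(unique(species[duplicated(species)]), collapse = ", "))
  if (is.null(names(partition)))
    names(partition) <- paste0("C", seq_along(partition))
  if (is.null(names(subclusters)))
    names(subclusters) <- paste0("S", seq_along(subclusters))
  extra <- setdiff(unlist(subclusters), species)
  if (length(extra))
    stop("subcluster species not in partition: ",
         paste(extra, collapse = ", "))
  structure(list(partition = lapply(partition, as.character),
                 subclusters = lapply(subclusters, as.character)),
            class = "cluster_pattern")
}

# Precompute bitmask representation of a pattern against a fixed species
# (column) ordering.
.pattern_masks <- function(pattern, species) {
  missing <- setdiff(unlist(pattern$partition), species)
  if (length(missing))
    stop("pattern species absent from matrix: ",
         paste(missing, collapse = ", "))
  if (length(setdiff(species, unlist(pattern$partition))))
    stop("pattern does not cover all matrix species")
  mask_of <- function(set) sum(2^(match(set, species) - 1))
  list(k = length(pattern$partition),
       part_masks = sort(unname(vapply(pattern$partition, mask_of,
                                       numeric(1)))),
       sub_masks = unname(vapply(pattern$subclusters, mask_of,
                                 numeric(1))),
       leaf_masks = 2^(seq_along(species) - 1),
       full_mask = sum(2^(seq_along(species) - 1)))
}

# Cluster one assays x species value matrix and score it against
# precomputed pattern masks.  Returns c(partition_match, clade flags...).
.recap_flags <- function(values, pinfo) {
  D <- as.matrix(stats::dist(t(values), method = "manhattan"))
  core <- .cl_core(D, k_snapshot = pinfo$k)
  part_ok <- identical(sort(core$snapshot), pinfo$part_masks)
  clade_pool <- c(pinfo$leaf_masks, pinfo$full_mask, core$mmasks)
  c(part_ok, pinfo$sub_masks %in% clade_pool)
}

#' Check a single tree against a reference cluster pattern
#'
#' The per-draw predicate behind the recapitulation rate: does the k-way
#' cut of this tree equal the reference partition (as unordered sets), and
#' is each named subcluster a clade?
#'
#' @param tree An [stats::hclust] over the pattern's species.
#' @param pattern A [cluster_pattern()].
#' @return List with `partition_match` (flag) and `subclusters` (named
#'   logical vector of clade flags).
#' @export
recapitulation_check <- function(tree, pattern) {
  if (!setequal(tree$labels, unlist(pattern$partition)))
    stop("tree leaves do not match pattern species")
  pinfo <- .pattern_masks(pattern, tree$labels)
  cut <- cut_partition(tree, pinfo$k)
  cut_masks <- sort(unname(vapply(cut, function(s)
    sum(2^(match(s, tree$labels) - 1)), numeric(1))))
  list(partition_match = identical(cut_masks, pinfo$part_masks),
       subclusters = vapply(pattern$subclusters, function(s)
         is_clade(tree, s), logical(1)))
}

#' Bootstrap recapitulation of a cluster pattern
#'
#' The core resampling analysis: draw `B` bootstrap samples of assays
#' (rows, with replacement, at the original row count), re-cluster the
#' species of each resampled matrix (Manhattan distance, complete
#' linkage), and count how often the k-way cut equals the reference
#' partition and each named subcluster reappears as a clade.  The overall
#' recapitulation rate requires the partition match and every subcluster
#' jointly; per-criterion rates are also reported so either convention can
#' be read out.
#'
#' `mode = "stratified"` (the default, and the procedure's literal design:
#' resampling assays according to the presence/absence of each coregulator)
#' resamples rows within strata of identical coregulator presence/absence
#' signatures, preserving stratum sizes, so every draw keeps the original
#' coregulator composition of the assay roster.  `mode = "plain"`
#' resamples all rows freely -- the ordinary bootstrap, under which draws
#' that happen to contain few informative assays depress the rate.
#'
#' @param x A row-normalized [assay_matrix()] (see [row_normalize()]).
#' @param pattern A [cluster_pattern()] over the matrix's species.
#' @param B Number of bootstrap draws (10,000 by default); >= 1.
#' @param seed Integer seed; one seeded generator drives the whole run,
#'   drawing B x row-count indices in draw order.
#' @param mode `"stratified"` (default) or `"plain"`.
#' @param renormalize Re-apply row normalization to each resampled matrix
#'   (sensitivity analysis; z-scoring is per-row and commutes with row
#'   resampling, so the default is `FALSE`).
#' @param row_norm Normalization used when `renormalize = TRUE`.
#' @return Object of class `stability_report`: `n_bootstrap`, `seed`,
#'   `mode`, `overall_recapitulation` (joint), `partition_recapitulation`,
#'   `subcluster_recapitulation` (named rates).
#' @examples
#' sim <- simulate_assay_matrix(default_species_groups(), seed = 1)
#' m <- row_normalize(sim$matrix)
#' bootstrap_recapitulation(m, cluster_pattern(sim$truth$true_partition),
#'                          B = 100, seed = 1)
#' @export
bootstrap_recapitulation <- function(x, pattern, B = 10000L, seed = 1L,
                                     mode = c("stratified", "plain"),
                                     renormalize = FALSE,
                                     row_norm = "zscore") {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "assay_matrix"))
  if (B < 1) stop("`B` must be >= 1")
  values <- x$values
  nr <- nrow(values)
  pinfo <- .pattern_masks(pattern, colnames(values))

  set.seed(seed)
  if (mode == "plain") {
    idx <- matrix(sample.int(nr, nr * B, replace = TRUE), nrow = B,
                  byrow = TRUE)
  } else {
    sig <- apply(as.matrix(x$annotations[COREGULATORS]), 1, paste,
                 collapse = "")
    strata <- split(seq_len(nr), sig)
    if (any(lengths(strata) == 0)) stop("empty stratum in stratified mode")
    idx <- matrix(0L, B, nr)
    pos <- 1L
    for (str in strata) {
      ms <- length(str)
      draw <- matrix(str[sample.int(ms, ms * B, replace = TRUE)],
                     nrow = B, byrow = TRUE)
      idx[, pos:(pos + ms - 1L)] <- draw
      pos <- pos + ms
    }
  }

  n_sub <- length(pinfo$sub_masks)
  counts <- numeric(1L + n_sub)
  joint <- 0
  for (b in seq_len(B)) {
    vals <- values[idx[b, ], , drop = FALSE]
    if (renormalize) vals <- row_normalize(vals, method = row_norm)
    fl <- .recap_flags(vals, pinfo)
    counts <- counts + fl
    if (all(fl)) joint <- joint + 1
  }
  structure(list(
    n_bootstrap = as.integer(B), seed = as.integer(seed), mode = mode,
    renormalize = renormalize,
    overall_recapitulation = joint / B,
    partition_recapitulation = counts[1] / B,
    subcluster_recapitulation =
      stats::setNames(counts[-1] / B, names(pattern$subclusters))),
    class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("stability_report (B = %d, seed = %d, mode = %s)\n",
              x$n_bootstrap, x$seed, x$mode))
  cat(sprintf("  overall recapitulation:   %.4f\n",
              x$overall_recapitulation))
  cat(sprintf("  partition recapitulation: %.4f\n",
              x$partition_recapitulation))
  for (nm in names(x$subcluster_recapitulation))
    cat(sprintf("  subcluster %-10s      %.4f\n", paste0(nm, ":"),
                x$subcluster_recapitulation[[nm]]))
  invisible(x)
}

#' Rank coregulators as drivers of the cluster pattern
#'
#' Leave-one-coregulator-out importance: for each coregulator `g`, the
#' bootstrap recapitulation rate is recomputed on the assay subset with
#' all `g`-annotated assays removed; the importance of `g` is the drop
#' `r_full - r_g`.  The lower the agreement with the original pattern
#' once `g`'s assays are gone, the higher the inferred importance of `g`
#' for the species cluster structure.  Per-subcluster rate drops are
#' reported alongside the overall drop.
#'
#' @param x A row-normalized [assay_matrix()].
#' @param pattern A [cluster_pattern()].
#' @param B Bootstrap draws per rate.
#' @param seed Integer master seed; per-coregulator sub-seeds are derived
#'   from it deterministically.
#' @param mode Resampling mode of the inner bootstraps (see
#'   [bootstrap_recapitulation()]).
#' @param coregulators Coregulators to score (default all of
#'   [COREGULATORS]).  A coregulator absent from every assay gets
#'   importance 0 with a warning and is flagged `vacuous`.
#' @return Object of class `coregulator_importance`: named `importance`
#'   vector, full-matrix rates, per-coregulator leave-out rates,
#'   per-subcluster drops (matrix), and the `vacuous` flag vector.
#' @export
coregulator_importance <- function(x, pattern, B = 1000L, seed = 1L,
                                   mode = c("stratified", "plain"),
                                   coregulators = COREGULATORS) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "assay_matrix"))
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L,
                          length(coregulators) + 1L)
  full <- bootstrap_recapitulation(x, pattern, B = B, seed = sub_seeds[1],
                                   mode = mode)

  nsub <- length(pattern$subclusters)
  importance <- stats::setNames(numeric(length(coregulators)),
                                coregulators)
  r_leaveout <- stats::setNames(rep(NA_real_, length(coregulators)),
                                coregulators)
  vacuous <- stats::setNames(logical(length(coregulators)), coregulators)
  sub_drop <- matrix(NA_real_, length(coregulators), nsub,
                     dimnames = list(coregulators,
                                     names(pattern$subclusters)))
  for (i in seq_along(coregulators)) {
    g <- coregulators[i]
    flag <- x$annotations[[g]]
    if (is.null(flag)) stop("unknown coregulator: ", g)
    if (!any(flag)) {
      warning("coregulator `", g,
              "` is absent from every assay; importance reported as 0")
      vacuous[i] <- TRUE
      importance[i] <- 0
      next
    }
    keep <- which(!flag)
    if (length(keep) < 2)
      stop("removing `", g, "` assays leaves fewer than 2 rows")
    sub <- assay_matrix(x$values[keep, , drop = FALSE],
                        x$annotations[keep, , drop = FALSE])
    rep_g <- bootstrap_recapitulation(sub, pattern, B = B,
                                      seed = sub_seeds[i + 1], mode = mode)
    r_leaveout[i] <- rep_g$overall_recapitulation
    importance[i] <- full$overall_recapitulation - r_leaveout[i]
    sub_drop[i, ] <- full$subcluster_recapitulation -
      rep_g$subcluster_recapitulation
  }
  structure(list(importance = importance,
                 r_full = full$overall_recapitulation,
                 r_leaveout = r_leaveout,
                 subcluster_drop = sub_drop,
                 vacuous = vacuous,
                 n_bootstrap = as.integer(B), seed = as.integer(seed),
                 mode = "leave-out"),
            class = "coregulator_importance")
}

#' @export
print.coregulator_importance <- function(x, ...) {
  cat(sprintf("coregulator importance (leave-out, B = %d, seed = %d)\n",
              x$n_bootstrap, x$seed))
  cat(sprintf("  full-matrix recapitulation: %.4f\n", x$r_full))
  ord <- order(x$importance, decreasing = TRUE)
  for (i in ord)
    cat(sprintf("  %-8s importance %+.4f (leave-out rate %s)%s\n",
                names(x$importance)[i], x$importance[i],
                ifelse(is.na(x$r_leaveout[i]), "NA",
                       sprintf("%.4f", x$r_leaveout[i])),
                if (x$vacuous[i]) "  [absent from all assays]" else ""))
  invisible(x)
}
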