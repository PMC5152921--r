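#' Normalize firefly luminescence to the internal luciferase control
#'
#' First step of the dual-luciferase chain: divide the firefly reporter
#' signal by the co-transfected internal control (Renilla) signal of the
#' same well, cancelling well-to-well transfection efficiency.
#'
#' @param firefly Firefly luminescence (vectorised).
#' @param internal_control Internal-control luminescence; must be > 0.
#' @return `firefly / internal_control`.
#' @examples
#' normalize_to_control(500, 100)  # 5
#' @export
normalize_to_control <- function(firefly, internal_control) {
  if (any(internal_control <= 0))
    stop("internal control luminescence must be > 0")
  firefly / internal_control
}

#' Fold activation / fold interaction relative to a reference
#'
#' The ratio of mean control-normalised sample signal to mean
#' control-normalised reference signal.  The same operation serves the
#' three normalization baselines of the assay designs -- empty vector
#' (fold activation), receptor alone (coregulator effect), and VP16-VDR
#' without bait (two-hybrid fold interaction) -- selected by the caller
#' through the choice of `reference_ratios`.
#'
#' @param sample_ratios Control-normalised ratios of the sample wells.
#' @param reference_ratios Control-normalised ratios of the reference
#'   wells; mean must be > 0.
#' @return Scalar fold change.
#' @examples
#' fold_activation(c(7.2, 7.2, 7.2, 7.2), c(2, 2, 2, 2))  # 3.6
#' @export
fold_activation <- function(sample_ratios, reference_ratios) {
  if (!length(sample_ratios) || !length(reference_ratios))
    stop("sample and reference ratio lists must be nonempty")
  ref <- mean(reference_ratios)
  if (ref <= 0) stop("reference mean must be > 0")
  mean(sample_ratios) / ref
}

#' Mean and SEM of experiment-level folds
#'
#' Experiments -- not wells -- are the unit of replication: folds are
#' computed per experiment and then averaged (n = 3 in the reference
#' design), with the standard error of that mean.
#'
#' @param per_experiment_folds Numeric vector of per-experiment folds,
#'   length >= 2.
#' @return List with `mean`, `sem`, `n`.
#' @examples
#' summarize_fold(c(3.0, 3.6, 4.2))  # mean 3.6, sem ~0.346
#' @export
summarize_fold <- function(per_experiment_folds) {
  n <- length(per_experiment_folds)
  if (n < 2) stop("need >= 2 experiment-level folds for a SEM")
  list(mean = mean(per_experiment_folds),
       sem = stats::sd(per_experiment_folds) / sqrt(n),
       n = n)
}

#' Per-experiment folds for one assay/receptor combination
#'
#' @param records Luciferase record table (see [simulate_luciferase()]).
#' @param receptor Receptor/construct of interest.
#' @param reference Reference construct within the same assay.
#' @return Numeric vector of folds, one per experiment present.
#' @keywords internal
experiment_folds <- function(records, receptor, reference = "empty") {
  ratios <- normalize_to_control(records$firefly, records$internal_control)
  exps <- sort(unique(records$experiment))
  vapply(exps, function(e) {
    s <- ratios[records$receptor == receptor & records$experiment == e]
    r <- ratios[records$receptor == reference & records$experiment == e]
    if (!length(s) || !length(r))
      stop("no wells for receptor `", receptor, "` or reference `",
           reference, "` in experiment ", e)
    fold_activation(s, r)
  }, numeric(1))
}

#' Assemble the annotated assay-response matrix from luciferase records
#'
#' Builds one row per assay definition (a unique combination of assay
#' class, ligand and coregulator set) and one column per species; each
#' cell is the mean of per-experiment folds of that receptor against the
#' assay's reference construct (`empty` for transactivation assays,
#' `vp16-only` for two-hybrid assays, falling back to `empty` when no
#' `vp16-only` wells exist).  Annotations are carried from the layout into
#' the Pickett structure of the returned matrix.
#'
#' @param records Well-level record table: columns `assay`, `receptor`,
#'   `firefly`, `internal_control`, `experiment` (e.g. rbind-ed outputs of
#'   [simulate_luciferase()]).
#' @param layout Assay layout data frame (see [default_assay_layout()]);
#'   `layout$assay` must match the `assay` values in `records` and be
#'   unique.
#' @param species Character vector of receptor variants to place in
#'   columns.
#' @param fill Optional numeric used for (assay, species) combinations
#'   absent from `records`; default `NULL` makes a missing cell an error.
#'   `fill = 1` encodes "no activation".
#' @return An [assay_matrix()].
#' @export
assemble_assay_matrix <- function(records, layout, species, fill = NULL) {
  layout <- as.data.frame(layout)
  if (anyDuplicated(layout$assay))
    stop("duplicate assay definitions in layout: ",
         paste(unique(layout$assay[duplicated(layout$assay)]),
               collapse = ", "))
  missing_sp <- setdiff(species, unique(records$receptor))
  if (length(missing_sp) && is.null(fill))
    stop("species absent from records: ",
         paste(missing_sp, collapse = ", "))
  values <- matrix(NA_real_, nrow(layout), length(species),
                   dimnames = list(layout$assay, species))
  for (i in seq_len(nrow(layout))) {
    a <- layout$assay[i]
    rec <- records[records$assay == a, , drop = FALSE]
    reference <- if (identical(layout$assay_class[i], "M2H") &&
                     "vp16-only" %in% rec$receptor) "vp16-only" else "empty"
    for (sp in species) {
      sub <- rec[rec$receptor %in% c(sp, reference), , drop = FALSE]
      if (!sp %in% sub$receptor || !reference %in% sub$receptor) {
        if (is.null(fill))
          stop("missing cell: assay `", a, "`, species `", sp,
               "` (no fill policy set)")
        values[i, sp] <- fill
      } else {
        values[i, sp] <- mean(experiment_folds(sub, sp, reference))
      }
    }
  }
  assay_matrix(values, layout)
}
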