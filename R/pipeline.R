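#' Build a validated pipeline configuration
#'
#' Collects every knob of the end-to-end run -- synthetic design, binding
#' constants, normalization, bootstrap size and mode -- with the package
#' defaults, and validates it.  Fields can come from a YAML file
#' (`pipeline_config(file = ...)`) with individual arguments overriding
#' file keys.
#'
#' @param seed Master seed; every stage seed is derived from it.
#' @param species_groups Planted partition (list of character vectors).
#' @param effect_size,noise_sd,drivers Assay-matrix generator settings
#'   (see [simulate_assay_matrix()]).
#' @param true_ki_uM,kd_nM,radioligand_nM,binding_cv Binding-simulation
#'   and fit settings (see [simulate_competition_curve()]).
#' @param true_folds,luciferase_cv Reporter-simulation settings (see
#'   [simulate_luciferase()]).
#' @param row_norm Row normalization: `"zscore"`, `"minmax"` or `"none"`.
#' @param B Bootstrap draws.
#' @param mode Bootstrap mode, `"stratified"` (default) or `"plain"`.
#' @param file Optional YAML file of config keys.
#' @param ... Further overrides of file keys.
#' @return Validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            species_groups = default_species_groups(),
                            effect_size = 6,
                            noise_sd = 1,
                            drivers = c("RXR_WT", "SRC1"),
                            true_ki_uM = 9.5,
                            kd_nM = 1,
                            radioligand_nM = 4,
                            binding_cv = 0.05,
                            true_folds = c(empty = 1, zfVDRa = 1.8,
                                           hVDR = 3.6),
                            luciferase_cv = 0.2,
                            row_norm = "zscore",
                            B = 1000L,
                            mode = "stratified",
                            file = NULL,
                            ...) {
  cfg <- list(seed = seed, species_groups = species_groups,
              effect_size = effect_size, noise_sd = noise_sd,
              drivers = drivers, true_ki_uM = true_ki_uM, kd_nM = kd_nM,
              radioligand_nM = radioligand_nM, binding_cv = binding_cv,
              true_folds = true_folds, luciferase_cv = luciferase_cv,
              row_norm = row_norm, B = B, mode = mode)
  if (!is.null(file)) {
    from_file <- yaml::read_yaml(file)
    unknown <- setdiff(names(from_file), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(from_file)] <- from_file
    if (!is.null(from_file$true_folds))
      cfg$true_folds <- unlist(from_file$true_folds)
    # arguments given explicitly in the call override file keys
    supplied <- intersect(names(match.call())[-1],
                          setdiff(names(cfg), "file"))
    for (nm in supplied) cfg[[nm]] <- get(nm)
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_config(cfg)
}

validate_config <- function(cfg) {
  fail <- function(field, why)
    stop("invalid config field `", field, "`: ", why, call. = FALSE)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1)
    fail("seed", "must be a single integer")
  if (!is.list(cfg$species_groups) || length(cfg$species_groups) < 2)
    fail("species_groups", "must list >= 2 groups")
  if (cfg$noise_sd < 0) fail("noise_sd", "must be >= 0")
  if (cfg$true_ki_uM <= 0) fail("true_ki_uM", "must be > 0")
  if (cfg$kd_nM <= 0) fail("kd_nM", "must be > 0")
  if (cfg$radioligand_nM < 0) fail("radioligand_nM", "must be >= 0")
  if (cfg$binding_cv < 0) fail("binding_cv", "must be >= 0")
  if (any(cfg$true_folds <= 0)) fail("true_folds", "folds must be > 0")
  if (cfg$luciferase_cv < 0) fail("luciferase_cv", "must be >= 0")
  if (!cfg$row_norm %in% c("zscore", "minmax", "none"))
    fail("row_norm", "must be zscore, minmax or none")
  if (!is.numeric(cfg$B) || cfg$B < 1) fail("B", "must be >= 1")
  if (!cfg$mode %in% c("plain", "stratified"))
    fail("mode", "must be plain or stratified")
  structure(cfg, class = "pipeline_config")
}

#' Run the full synthetic-to-stability pipeline
#'
#' Executes the stages in order -- simulate (binding curve, luciferase
#' records, assay matrix), binding fit, reporter folds, matrix assembly
#' checkpointing, clustering, bootstrap stability and coregulator
#' importance -- writing per-stage artifacts under `out_dir` and one JSON
#' summary.  Every run is fully determined by the config: stage seeds are
#' derived from the master seed, no timestamps are written, so two runs of
#' the same config are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return The summary list, invisibly; artifacts on disk:
#'   `binding/curve.csv`, `binding/fit.json`, `reporter/luciferase.csv`,
#'   `reporter/folds.json`, `matrix.tsv` (+ `matrix.json` sidecar),
#'   `cluster/dendrogram.nwk`, `cluster/partition.json`,
#'   `stability/report.json`, `truth.json`, `summary.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  config <- validate_config(unclass(config))
  if (missing(out_dir)) stop("`out_dir` is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (sub in c("binding", "reporter", "cluster", "stability"))
    dir.create(file.path(out_dir, sub), showWarnings = FALSE)
  path <- function(...) file.path(out_dir, ...)
  wjson <- function(x, p)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }

  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 5L)

  sim <- stage("simulate", {
    mat_sim <- simulate_assay_matrix(
      config$species_groups, effect_size = config$effect_size,
      noise_sd = config$noise_sd, drivers = config$drivers,
      seed = seeds[1])
    bind_sim <- simulate_competition_curve(
      true_ki_uM = config$true_ki_uM, kd_nM = config$kd_nM,
      radioligand_nM = config$radioligand_nM, cv = config$binding_cv,
      seed = seeds[2])
    luc <- simulate_luciferase(config$true_folds, cv = config$luciferase_cv,
                               seed = seeds[3])
    utils::write.csv(bind_sim$curve, path("binding", "curve.csv"),
                     row.names = FALSE)
    utils::write.csv(luc, path("reporter", "luciferase.csv"),
                     row.names = FALSE)
    wjson(list(assay_matrix = unclass(mat_sim$truth),
               binding = unclass(bind_sim$truth),
               luciferase = unclass(attr(luc, "truth"))),
          path("truth.json"))
    list(mat = mat_sim$matrix, truth = mat_sim$truth,
         curve = bind_sim$curve, luc = luc)
  })

  fit <- stage("binding-fit", {
    f <- fit_competition(sim$curve, kd_nM = config$kd_nM)
    wjson(unclass(f), path("binding", "fit.json"))
    f
  })

  folds <- stage("reporter-fold", {
    receptors <- setdiff(unique(sim$luc$receptor), "empty")
    out <- lapply(stats::setNames(receptors, receptors), function(r)
      summarize_fold(experiment_folds(sim$luc, r)))
    wjson(out, path("reporter", "folds.json"))
    out
  })

  mat <- stage("assemble", {
    write_assay_matrix(sim$mat, path("matrix.tsv"))
    read_assay_matrix(path("matrix.tsv"))  # checkpoint: lossless round-trip
  })

  clust <- stage("cluster", {
    norm <- row_normalize(mat, method = config$row_norm)
    tree <- complete_linkage(species_distance(norm))
    to_newick(tree, path("cluster", "dendrogram.nwk"))
    partition <- cut_partition(tree, length(config$species_groups))
    wjson(list(k = length(config$species_groups), partition = partition),
          path("cluster", "partition.json"))
    list(norm = norm, tree = tree, partition = partition)
  })

  stab <- stage("stability", {
    pattern <- cluster_pattern(sim$truth$true_partition)
    report <- bootstrap_recapitulation(clust$norm, pattern, B = config$B,
                                       seed = seeds[4], mode = config$mode)
    imp <- coregulator_importance(clust$norm, pattern, B = config$B,
                                  seed = seeds[5])
    wjson(list(recapitulation = unclass(report),
               importance = list(
                 importance = as.list(imp$importance),
                 r_full = imp$r_full,
                 r_leaveout = as.list(imp$r_leaveout),
                 vacuous = as.list(imp$vacuous))),
          path("stability", "report.json"))
    list(report = report, importance = imp)
  })

  summary <- list(
    provenance = list(package = "vdrfun",
                      version = as.character(utils::packageVersion("vdrfun")),
                      seed = config$seed,
                      config = config[setdiff(names(config),
                                              "species_groups")],
                      species_groups = config$species_groups),
    binding = list(ic50_uM = fit$ic50_uM, ki_uM = fit$ki_uM,
                   converged = fit$converged),
    folds = folds,
    cluster = list(partition = clust$partition),
    stability = list(
      overall_recapitulation = stab$report$overall_recapitulation,
      partition_recapitulation = stab$report$partition_recapitulation,
      subcluster_recapitulation =
        as.list(stab$report$subcluster_recapitulation),
      importance = as.list(stab$importance$importance)))
  wjson(summary, path("summary.json"))
  invisible(summary)
}
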