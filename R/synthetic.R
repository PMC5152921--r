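#' Simulate a coregulator-annotated assay-response matrix with planted
#' cluster structure
#'
#' Generates a species-by-assay response matrix emulating the statistical
#' structure of the multi-species functional-assay summary: two (or more)
#' planted species clusters whose separation is carried exclusively by the
#' assays annotated with "driver" coregulators.  Driver-annotated assays
#' have group means separated by `effect_size` noise-SD units between
#' consecutive groups; all other assays have identical group means.
#' Additive Gaussian noise with standard deviation `noise_sd` is applied to
#' every cell.  When `noise_sd` is zero the separation amplitude is
#' `effect_size` itself (effect size on a unit reference SD), so the
#' zero-noise matrix is an exact two-level image of the planted structure.
#'
#' @param species_groups List of >= 2 character vectors, the planted
#'   partition of species into functional clusters (e.g.
#'   [default_species_groups()]).  Groups must be non-empty and species
#'   names unique across groups.
#' @param assays Assay layout data frame as returned by
#'   [default_assay_layout()].
#' @param effect_size Between-group separation of driver assays, in units
#'   of `noise_sd` (default 6).
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (default 1); must be >= 0.
#' @param drivers Character vector of coregulator names whose annotated
#'   assays carry the group separation (default `c("RXR_WT", "SRC1")`).
#' @param seed Integer seed; the same seed reproduces the matrix exactly.
#'
#' @return List with elements
#'   \describe{
#'     \item{matrix}{the simulated [assay_matrix()],}
#'     \item{truth}{a `simulation_truth` record of the planted partition,
#'       driver set, effect size, noise SD and seed.}
#'   }
#' @examples
#' sim <- simulate_assay_matrix(default_species_groups(), seed = 1)
#' sim$matrix
#' @export
simulate_assay_matrix <- function(species_groups,
                                  assays = default_assay_layout(),
                                  effect_size = 6,
                                  noise_sd = 1,
                                  drivers = c("RXR_WT", "SRC1"),
                                  seed = 1L) {
  if (!is.list(species_groups) || length(species_groups) < 2)
    stop("`species_groups` must be a list of at least 2 groups")
  if (any(lengths(species_groups) == 0))
    stop("empty species group")
  species <- unlist(species_groups, use.names = FALSE)
  if (length(species) < 2) stop("need at least 2 species in total")
  if (anyDuplicated(species))
    stop("duplicate species name: ",
         paste(unique(species[duplicated(species)]), collapse = ", "))
  assays <- as.data.frame(assays)
  if (nrow(assays) < 2) stop("need at least 2 assays")
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("negative noise_sd")
  bad <- setdiff(drivers, COREGULATORS)
  if (length(bad))
    stop("unknown driver coregulator: ", paste(bad, collapse = ", "))

  n_assay <- nrow(assays)
  group_of <- rep(seq_along(species_groups), lengths(species_groups))
  driver_row <- if (length(drivers)) {
    Reduce(`|`, lapply(drivers, function(g) assays[[g]]))
  } else {
    rep(FALSE, n_assay)
  }
  delta <- effect_size * if (noise_sd > 0) noise_sd else 1

  set.seed(seed)
  means <- outer(ifelse(driver_row, delta, 0), group_of - 1)
  values <- means + matrix(stats::rnorm(n_assay * length(species),
                                        sd = noise_sd),
                           n_assay, length(species))
  dimnames(values) <- list(assays$assay, species)

  truth <- simulation_truth(
    seed = seed,
    true_partition = lapply(species_groups, as.character),
    driver_coregulators = drivers,
    effect_size = effect_size,
    noise_sd = noise_sd)
  list(matrix = assay_matrix(values, assays), truth = truth)
}

#' Simulate a competitive radioligand-binding experiment
#'
#' Generates tube-level scintillation counts for a one-site competition
#' design: a fixed concentration of radiolabelled hormone (`radioligand_nM`,
#' 4 nM in the reference design) competed by a dilution series of cold
#' competitor (`concentrations_M`, spanning 0 to 1 mM by default).  The
#' planted IC50 is derived from `true_ki_uM` by inverting the Cheng-Prusoff
#' relation, `IC50 = Ki * (1 + L/Kd)`.  Expected specific binding follows
#' the one-site competition curve
#' `S(c) = bottom + (top - bottom) / (1 + c/IC50)`; nonspecific binding is
#' a flat floor equal to `ns_fraction` of total binding at c = 0, and
#' total = specific + nonspecific.  Each simulated tube receives
#' multiplicative Gaussian noise with coefficient of variation `cv`.
#'
#' @param true_ki_uM Planted inhibition constant of the competitor, uM.
#' @param kd_nM Dissociation constant of the hot ligand, nM.
#' @param radioligand_nM Hot-ligand concentration, nM.
#' @param concentrations_M Competitor concentrations in molar; must be
#'   nonnegative and include 0 (the no-competitor tubes).
#' @param top,bottom Plateaus of the specific-binding curve, counts.
#' @param cv Coefficient of variation of the multiplicative tube noise.
#' @param replicates Technical replicates per concentration per experiment.
#' @param n_experiments Independent experiments (3 in the reference design).
#' @param ns_fraction Nonspecific binding as a fraction of total binding at
#'   c = 0 (flat across the series).
#' @param seed Integer seed.
#'
#' @return List with elements
#'   \describe{
#'     \item{curve}{a `competition_curve`: long data frame with columns
#'       `conc_M`, `lysate` (`"vdr"` = total, `"empty"` = nonspecific),
#'       `counts`, `experiment`, `replicate`, and attribute
#'       `radioligand_nM`,}
#'     \item{truth}{a `simulation_truth` with the planted Ki, Kd, derived
#'       IC50 and curve parameters.}
#'   }
#' @examples
#' sim <- simulate_competition_curve(true_ki_uM = 5, kd_nM = 1, cv = 0,
#'                                   seed = 1)
#' sim$truth$true_ic50_uM  # 5 * (1 + 4/1) = 25
#' @export
simulate_competition_curve <- function(true_ki_uM = 9.5,
                                       kd_nM = 1,
                                       radioligand_nM = 4,
                                       concentrations_M =
                                         c(0, 10^seq(-8, -3, by = 0.5)),
                                       top = 1000,
                                       bottom = 0,
                                       cv = 0.05,
                                       replicates = 2L,
                                       n_experiments = 3L,
                                       ns_fraction = 0.2,
                                       seed = 1L) {
  if (kd_nM <= 0) stop("kd must be > 0")
  if (true_ki_uM <= 0) stop("true_ki must be > 0")
  if (radioligand_nM < 0) stop("radioligand concentration must be >= 0")
  if (cv < 0) stop("cv must be >= 0")
  if (any(concentrations_M < 0)) stop("negative concentration")
  if (!any(concentrations_M == 0))
    stop("`concentrations_M` must include 0 (no-competitor tubes)")
  conc <- sort(unique(concentrations_M))

  ic50_uM <- true_ki_uM * (1 + radioligand_nM / kd_nM)
  spec <- bottom + (top - bottom) / (1 + conc / (ic50_uM * 1e-6))
  ns_level <- ns_fraction / (1 - ns_fraction) * spec[1]  # flat floor
  total <- spec + ns_level

  set.seed(seed)
  grid <- expand.grid(replicate = seq_len(replicates),
                      experiment = seq_len(n_experiments),
                      conc_i = seq_along(conc))
  noisy <- function(mu) mu * (1 + stats::rnorm(nrow(grid), sd = cv))
  tot_counts <- noisy(total[grid$conc_i])
  ns_counts <- noisy(rep(ns_level, length(conc))[grid$conc_i])
  curve <- rbind(
    data.frame(conc_M = conc[grid$conc_i], lysate = "vdr",
               counts = tot_counts, experiment = grid$experiment,
               replicate = grid$replicate, stringsAsFactors = FALSE),
    data.frame(conc_M = conc[grid$conc_i], lysate = "empty",
               counts = ns_counts, experiment = grid$experiment,
               replicate = grid$replicate, stringsAsFactors = FALSE))
  curve <- curve[order(curve$conc_M, curve$lysate,
                       curve$experiment, curve$replicate), ]
  rownames(curve) <- NULL
  attr(curve, "radioligand_nM") <- radioligand_nM
  class(curve) <- c("competition_curve", "data.frame")

  truth <- simulation_truth(
    seed = seed, true_ki_uM = true_ki_uM, true_kd_nM = kd_nM,
    radioligand_nM = radioligand_nM, true_ic50_uM = ic50_uM,
    top = top, bottom = bottom, cv = cv,
    ns_level = ns_level)
  list(curve = curve, truth = truth)
}

#' Simulate a dual-luciferase reporter experiment
#'
#' Generates well-level firefly and internal-control (Renilla) luminescence
#' for a set of constructs with planted fold effects.  Firefly signal is
#' `baseline * fold * eps` and the internal control `baseline * eps'`,
#' with `eps` lognormal with mean 1 and coefficient of variation `cv`, so
#' the control-normalised ratio of a construct recovers its planted fold
#' relative to the reference construct.  A reference construct `empty`
#' (fold 1) is added if not supplied.
#'
#' @param true_folds Named numeric vector mapping construct name to planted
#'   fold; all folds must be > 0.
#' @param baseline Baseline luminescence of the reference construct; > 0.
#' @param cv Coefficient of variation of the lognormal well noise; >= 0.
#' @param wells Replicate wells per construct per experiment (4 in the
#'   reference design).
#' @param n_experiments Independent experiments (3 in the reference
#'   design).
#' @param assay_class,ligand,assay Annotation columns copied into the
#'   output table.
#' @param seed Integer seed.
#'
#' @return Data frame with one row per well: `assay`, `assay_class`,
#'   `ligand`, `receptor` (construct), `firefly`, `internal_control`,
#'   `experiment`, `well`.  The planted parameters are attached as a
#'   `simulation_truth` in attribute `"truth"`.
#' @examples
#' rec <- simulate_luciferase(c(empty = 1, hVDR = 3.6), cv = 0, seed = 1)
#' with(rec, tapply(firefly / internal_control, receptor, mean))
#' @export
simulate_luciferase <- function(true_folds,
                                baseline = 1000,
                                cv = 0.2,
                                wells = 4L,
                                n_experiments = 3L,
                                assay_class = "TT",
                                ligand = "LCA",
                                assay = paste(assay_class, ligand, "none",
                                              sep = "_"),
                                seed = 1L) {
  if (is.null(names(true_folds)) || any(!nzchar(names(true_folds))))
    stop("`true_folds` must be a named vector (construct -> fold)")
  if (any(true_folds <= 0)) stop("nonpositive fold")
  if (baseline <= 0) stop("nonpositive baseline")
  if (cv < 0) stop("cv must be >= 0")
  if (wells < 1) stop("need at least 1 well")
  if (!"empty" %in% names(true_folds))
    true_folds <- c(empty = 1, true_folds)

  # lognormal with mean 1 and CV = cv
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- -sdlog^2 / 2
  set.seed(seed)
  grid <- expand.grid(well = seq_len(wells),
                      experiment = seq_len(n_experiments),
                      receptor = names(true_folds),
                      stringsAsFactors = FALSE)
  eps_f <- stats::rlnorm(nrow(grid), meanlog, sdlog)
  eps_c <- stats::rlnorm(nrow(grid), meanlog, sdlog)
  out <- data.frame(
    assay = assay, assay_class = assay_class, ligand = ligand,
    receptor = grid$receptor,
    firefly = baseline * true_folds[grid$receptor] * eps_f,
    internal_control = baseline * eps_c,
    experiment = grid$experiment, well = grid$well,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "truth") <- simulation_truth(
    seed = seed, true_folds = true_folds, baseline = baseline, cv = cv,
    wells = wells, n_experiments = n_experiments)
  out
}

#' Record of planted simulation parameters
#'
#' Every synthetic generator returns one of these alongside its data so
#' downstream estimates can be compared against ground truth.
#'
#' @param seed Integer seed used.
#' @param ... Named planted parameters (partition, drivers, Ki, folds, ...).
#' @return An object of class `simulation_truth` (a named list).
#' @export
simulation_truth <- function(seed, ...) {
  structure(c(list(seed = seed), list(...)), class = "simulation_truth")
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat("simulation_truth (seed", x$seed, ")\n")
  for (nm in setdiff(names(x), "seed")) {
    v <- x[[nm]]
    if (is.list(v))
      v <- paste(vapply(v, function(s) paste(s, collapse = "+"),
                        character(1)), collapse = " | ")
    cat(" ", nm, ":", paste(format(v), collapse = ", "), "\n")
  }
  invisible(x)
}
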