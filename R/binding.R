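#' Specific binding from total and nonspecific counts
#'
#' Specific binding at each competitor concentration is the mean of the
#' total-binding replicates (VDR-transfected lysate) minus the mean of the
#' nonspecific replicates (empty-vector lysate) at the same concentration.
#' Negative values are retained, not clamped: they carry information about
#' the noise floor and the fit's bottom plateau.
#'
#' @param total Either a `competition_curve` / long data frame with columns
#'   `conc_M`, `lysate`, `counts` (in which case `nonspecific` is ignored
#'   and the `"vdr"` / `"empty"` lysates are used), or a data frame with
#'   columns `conc_M` and `counts` holding total-binding tubes only.
#' @param nonspecific Data frame with columns `conc_M` and `counts` for the
#'   empty-vector tubes; must cover exactly the same concentration grid.
#'
#' @return Data frame with one row per concentration: `conc_M`,
#'   `total_mean`, `nonspecific_mean`, `specific`.
#' @examples
#' tot <- data.frame(conc_M = c(0, 0, 1e-6, 1e-6), counts = c(1000, 1000, 800, 800))
#' ns  <- data.frame(conc_M = c(0, 1e-6), counts = c(200, 200))
#' specific_binding(tot, ns)$specific  # 800, 600
#' @export
specific_binding <- function(total, nonspecific = NULL) {
  if (!is.null(total$lysate) && is.null(nonspecific)) {
    nonspecific <- total[total$lysate == "empty", c("conc_M", "counts")]
    total <- total[total$lysate == "vdr", c("conc_M", "counts")]
  }
  if (is.null(nonspecific))
    stop("supply `nonspecific` counts or a curve with a `lysate` column")
  for (d in list(total, nonspecific))
    if (!all(c("conc_M", "counts") %in% names(d)))
      stop("count tables need columns `conc_M` and `counts`")
  tm <- tapply(total$counts, total$conc_M, mean)
  nm <- tapply(nonspecific$counts, nonspecific$conc_M, mean)
  conc_t <- as.numeric(names(tm))
  conc_n <- as.numeric(names(nm))
  if (length(conc_t) != length(conc_n) || any(conc_t != conc_n))
    stop("mismatched concentration grids between total and nonspecific")
  data.frame(conc_M = conc_t,
             total_mean = as.numeric(tm),
             nonspecific_mean = as.numeric(nm),
             specific = as.numeric(tm) - as.numeric(nm))
}

#' Fit a one-site competition curve
#'
#' Least-squares fit of the one-site competition model
#' `S(c) = bottom + (top - bottom) / (1 + c/IC50)` (Hill slope fixed at
#' -1) to specific binding, pooling all tubes across experiments.  IC50 is
#' estimated on the log scale; the zero-concentration tubes enter the fit
#' directly (at c = 0 the model equals `top`, so they constrain the top
#' plateau without needing a log axis).  If `kd_nM` is supplied the fitted
#' IC50 is converted to Ki with [cheng_prusoff()] using the curve's
#' hot-ligand concentration.
#'
#' @param curve A `competition_curve` (see [simulate_competition_curve()])
#'   or any data frame with columns `conc_M`, `lysate`, `counts`.
#' @param kd_nM Optional dissociation constant of the hot ligand (nM),
#'   externally determined per receptor; never fitted here.
#' @param radioligand_nM Hot-ligand concentration (nM); defaults to the
#'   curve's `radioligand_nM` attribute.
#' @param conf_level Confidence level of the asymptotic IC50 interval.
#'
#' @return Object of class `binding_fit`: list with `ic50_uM`, `ki_uM`
#'   (NA unless `kd_nM` given), `kd_nM`, `top`, `bottom`, `ic50_ci_uM`,
#'   `converged`, `residual_sse`, `n_points`.
#' @examples
#' sim <- simulate_competition_curve(true_ki_uM = 5, kd_nM = 1, cv = 0, seed = 1)
#' fit <- fit_competition(sim$curve, kd_nM = 1)
#' c(fit$ic50_uM, fit$ki_uM)  # ~25, ~5
#' @export
fit_competition <- function(curve, kd_nM = NULL,
                            radioligand_nM = attr(curve, "radioligand_nM"),
                            conf_level = 0.95) {
  sb <- specific_binding(curve)
  conc_uM <- sb$conc_M * 1e6
  nz <- conc_uM[conc_uM > 0]
  if (length(unique(nz)) < 4)
    stop("need at least 4 distinct nonzero concentrations")
  if (max(nz) / min(nz) < 100)
    stop("nonzero concentrations must span at least 2 decades")
  if (diff(range(sb$specific)) == 0)
    stop("degenerate curve: all specific-binding responses are equal")

  # Levenberg-Marquardt on the raw sum of squares via nls.lm: unlike the
  # nls-model wrappers this handles exactly zero-residual (noise-free)
  # data, which the generator produces at cv = 0.
  start <- list(top = max(sb$specific), bottom = min(sb$specific),
                ic50 = exp(mean(log(range(nz)))))
  resid_fn <- function(p)
    sb$specific - (p$bottom + (p$top - p$bottom) / (1 + conc_uM / p$ic50))
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start, fn = resid_fn,
      lower = c(top = -Inf, bottom = -Inf, ic50 = min(nz) * 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                           ptol = 1e-12)),
    error = function(e) e)

  failed <- inherits(fit, "error")
  converged <- !failed && fit$info %in% c(1, 2, 3)
  if (failed) {
    out <- list(ic50_uM = NA_real_, ki_uM = NA_real_,
                kd_nM = if (is.null(kd_nM)) NA_real_ else kd_nM,
                top = NA_real_, bottom = NA_real_,
                ic50_ci_uM = c(NA_real_, NA_real_),
                converged = FALSE, residual_sse = NA_real_,
                n_points = nrow(sb), message = conditionMessage(fit))
    class(out) <- "binding_fit"
    return(out)
  }

  cf <- unlist(fit$par)
  ic50 <- cf[["ic50"]]
  sse <- fit$deviance
  # asymptotic covariance as in summary.nls.lm; CI on the log(IC50)
  # scale by the delta method, back-transformed
  se_ic50 <- tryCatch({
    rdf <- nrow(sb) - length(cf)
    covm <- chol2inv(chol(fit$hessian)) * sse / rdf
    sqrt(diag(covm))[[3]]
  }, error = function(e) NA_real_)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(log(ic50) + c(-1, 1) * z * se_ic50 / ic50)
  ki <- if (!is.null(kd_nM) && !is.null(radioligand_nM)) {
    cheng_prusoff(ic50, radioligand_nM, kd_nM)
  } else NA_real_
  out <- list(ic50_uM = ic50, ki_uM = ki,
              kd_nM = if (is.null(kd_nM)) NA_real_ else kd_nM,
              top = cf[["top"]], bottom = cf[["bottom"]],
              ic50_ci_uM = ci,
              converged = converged,
              residual_sse = sse,
              n_points = nrow(sb))
  class(out) <- "binding_fit"
  out
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("one-site competition fit\n")
  cat(sprintf("  IC50 = %.4g uM  [%.4g, %.4g]\n",
              x$ic50_uM, x$ic50_ci_uM[1], x$ic50_ci_uM[2]))
  if (!is.na(x$ki_uM))
    cat(sprintf("  Ki   = %.4g uM  (Kd = %.3g nM)\n", x$ki_uM, x$kd_nM))
  cat(sprintf("  top = %.4g, bottom = %.4g, SSE = %.4g, converged: %s\n",
              x$top, x$bottom, x$residual_sse, x$converged))
  invisible(x)
}

#' Cheng-Prusoff conversion of IC50 to Ki
#'
#' The inhibition constant of a competitor corrected for occupancy of the
#' receptor by the radioligand: `Ki = IC50 / (1 + L/Kd)`, where `L` is the
#' hot-ligand concentration and `Kd` its dissociation constant.  Units are
#' reconciled internally to molar; Ki is returned in the unit of the IC50.
#'
#' @param ic50 Half-maximal inhibitory concentration (in `ic50_unit`).
#' @param radioligand_conc Hot-ligand concentration `L` (in `conc_unit`);
#'   may be 0, in which case `Ki = IC50`.
#' @param kd Dissociation constant of the hot ligand (in `kd_unit`); > 0.
#' @param ic50_unit,conc_unit,kd_unit Units: one of `"M"`, `"mM"`, `"uM"`,
#'   `"nM"`, `"pM"`.
#' @return Ki in the unit of `ic50`.
#' @examples
#' cheng_prusoff(10, 4, 1)  # 10 / (1 + 4/1) = 2 uM
#' @export
cheng_prusoff <- function(ic50, radioligand_conc, kd,
                          ic50_unit = "uM", conc_unit = "nM",
                          kd_unit = "nM") {
  if (any(kd <= 0)) stop("kd must be > 0")
  if (any(ic50 <= 0)) stop("ic50 must be > 0")
  if (any(radioligand_conc < 0))
    stop("radioligand concentration must be >= 0")
  L <- to_molar(radioligand_conc, conc_unit)
  Kd <- to_molar(kd, kd_unit)
  to_molar(ic50, ic50_unit) / (1 + L / Kd) / unit_factor(ic50_unit)
}

unit_factor <- function(unit) {
  switch(unit,
         M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12,
         stop("unknown concentration unit: ", unit))
}

to_molar <- function(x, unit) x * unit_factor(unit)
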