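# Virtual patient cohort: patient-specific abundances of STAT1, STAT2, IRF9
# and USP18 plus residual plasma interferon, each log-normally distributed;
# antiviral-response metrics and desensitization thresholds per patient.

#' Log-normal parameters matched to a natural-scale mean and SD
#'
#' Moment matching: `mu = ln(m^2 / sqrt(m^2 + v))`, `sigma^2 = ln(1 + v/m^2)`.
#'
#' @param mean,sd mean and standard deviation on the natural scale (> 0).
#' @return list with `meanlog`, `sdlog`.
#' @export
lognormal_moments <- function(mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  v <- sd^2
  list(meanlog = log(mean^2 / sqrt(mean^2 + v)),
       sdlog = sqrt(log(1 + v / mean^2)))
}

#' Default cohort configuration
#'
#' Means and SDs (natural scale) of the five patient-specific quantities:
#' abundances of STAT1, STAT2, IRF9, USP18 (molecules/cell) and residual
#' plasma IFNa (pM). The plasma moments are the printed cohort statistics
#' (mean 0.0440, SD 0.0362 pM); the abundance moments are generator
#' configuration values centered on the nominal model and anchored to the
#' printed ranges (STAT1 1e5-1e6, STAT2 1e4-1e5 molecules per cell).
#'
#' @param n number of virtual patients (default 114, the study cohort size).
#' @return list with `n` and a data.frame `quantities` (quantity, mean, sd).
#' @export
cohort_config <- function(n = 114) {
  list(n = n, quantities = data.frame(
    quantity = c("STAT1", "STAT2", "IRF9", "USP18", "IFNa"),
    mean = c(4e5, 5e4, 8e3, 100, 0.0440),
    sd = c(2e5, 2.5e4, 4e3, 50, 0.0362)))
}

#' Sample a virtual patient cohort
#'
#' @param config from [cohort_config()] (or the same shape).
#' @param n number of patients; defaults to `config$n`.
#' @param seed RNG seed.
#' @return data.frame with one row per patient: `patient`, `STAT1`, `STAT2`,
#'   `IRF9`, `USP18` (molecules/cell), `IFNa` (pM).
#' @export
sample_cohort <- function(config = cohort_config(), n = config$n, seed = 1L) {
  q <- config$quantities
  stopifnot(n >= 1, all(q$mean > 0), all(q$sd >= 0))
  set.seed(seed)
  out <- data.frame(patient = seq_len(n))
  for (i in seq_len(nrow(q))) {
    mm <- lognormal_moments(q$mean[i], q$sd[i])
    out[[q$quantity[i]]] <- if (q$sd[i] == 0) rep(q$mean[i], n)
      else stats::rlnorm(n, mm$meanlog, mm$sdlog)
  }
  out
}

# trapezoid AUC of the occupied-promoter-site observable over [24, 28] h
.occ_auc <- function(pars, cond, variant, grid_by = 0.05, rtol = 1e-8,
                     atol = 1e-10) {
  g <- seq(0, 28, by = grid_by)
  tr <- simulate_model(pars, cond, t_grid = g, variant = variant,
                       rtol = rtol, atol = atol)
  o <- compute_observables(tr, pars, "OccSites")[, "OccSites"]
  s <- g >= 24
  sum(diff(g[s]) * (head(o[s], -1) + tail(o[s], -1)) / 2)
}

#' Antiviral response metrics for one patient
#'
#' Absolute response: the area under the occupied-promoter-site curve
#' (OccGASbs + OccISREbs) from 24 to 28 h after stimulation, minus the same
#' area without stimulation (composite trapezoid, grid step <= 0.05 h).
#' Relative response: the absolute response divided by the absolute response
#' of the matched zero-prestimulation reference.
#'
#' @param pars `ifndyn_parset` of the calibrated model.
#' @param patient one-row data.frame / list with `STAT1`, `STAT2`, `IRF9`,
#'   `USP18` abundances (molecules/cell), or `NULL` for the model as-is.
#' @param prestim_dose prestimulation dose (pM) applied at t = 0 (for cohort
#'   patients: the residual plasma interferon, constant over the first 24 h).
#' @param stim_dose stimulation dose added at 24 h (default 608 pM Roferon).
#' @param ligand ligand of both doses (default Roferon).
#' @param variant receptor variant.
#' @param grid_by AUC grid step (h), must be <= 0.05 for reported values.
#' @return list with `absolute`, `relative`, `reference_absolute`.
#' @export
antiviral_response <- function(pars, patient = NULL, prestim_dose = 0,
                               stim_dose = 608, ligand = "Roferon",
                               variant = "SOCS1_or_SOCS1xUSP18",
                               grid_by = 0.05) {
  ab <- if (is.null(patient)) NULL else
    unlist(patient[c("STAT1", "STAT2", "IRF9", "USP18")])
  mk <- function(pre, st) condition(prestim_dose = pre, stim_dose = st,
                                    stim_time = 24, ligand = ligand,
                                    abundance_overrides = ab)
  if (stim_dose == 0) {
    absolute <- 0   # stimulated and unstimulated runs coincide exactly
  } else {
    absolute <- .occ_auc(pars, mk(prestim_dose, stim_dose), variant, grid_by) -
      .occ_auc(pars, mk(prestim_dose, 0), variant, grid_by)
  }
  if (prestim_dose == 0) {
    ref <- absolute
    relative <- 1
  } else {
    ref <- if (stim_dose == 0) 0 else
      .occ_auc(pars, mk(0, stim_dose), variant, grid_by) -
        .occ_auc(pars, mk(0, 0), variant, grid_by)
    relative <- absolute / ref
  }
  list(absolute = absolute, relative = relative, reference_absolute = ref)
}

#' Desensitization threshold of a patient
#'
#' The prestimulation dose beyond which the relative antiviral response drops
#' below one, located by bisection on log10 dose to 1% relative tolerance.
#' When the response crosses one several times inside the range, the largest
#' dose below which the response is still >= 1 is returned and all bracketing
#' grid crossings are reported.
#'
#' @param pars,patient,stim_dose,ligand,variant,grid_by as in
#'   [antiviral_response()].
#' @param dose_range length-2 vector of prestimulation doses (pM) bracketing
#'   the threshold.
#' @param n_scan size of the coarse log-spaced scan used to bracket crossings.
#' @param rel_tol relative tolerance of the bisection (default 0.01).
#' @return list with `threshold` (pM, NA if none), `converged`, `crossings`
#'   (all sign-change brackets found on the scan grid), `scan` (data.frame
#'   dose, relative).
#' @export
desensitization_threshold <- function(pars, patient = NULL, stim_dose = 608,
                                      dose_range = c(0.1, 608),
                                      ligand = "Roferon",
                                      variant = "SOCS1_or_SOCS1xUSP18",
                                      grid_by = 0.05, n_scan = 9,
                                      rel_tol = 0.01) {
  relf <- function(d) antiviral_response(pars, patient, prestim_dose = d,
                                         stim_dose = stim_dose,
                                         ligand = ligand, variant = variant,
                                         grid_by = grid_by)$relative
  doses <- 10^seq(log10(dose_range[1]), log10(dose_range[2]),
                  length.out = n_scan)
  rel <- vapply(doses, relf, 0)
  scan <- data.frame(dose = doses, relative = rel)
  sgn <- sign(rel - 1)
  idx <- which(sgn[-length(sgn)] >= 0 & sgn[-1] < 0)
  if (length(idx) == 0)
    return(list(threshold = NA_real_, converged = FALSE,
                crossings = numeric(0), scan = scan))
  # bisection inside the LAST downward crossing (largest dose with rel >= 1)
  lo <- log10(doses[max(idx)]); hi <- log10(doses[max(idx) + 1])
  while ((10^hi - 10^lo) / 10^hi > rel_tol) {
    mid <- (lo + hi) / 2
    if (relf(10^mid) >= 1) lo <- mid else hi <- mid
  }
  list(threshold = 10^((lo + hi) / 2), converged = TRUE,
       crossings = vapply(idx, function(i) sqrt(doses[i] * doses[i + 1]), 0),
       scan = scan)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Rank correlation using average ranks for ties; the p-value comes from the
#' t approximation `t = r sqrt((n-2)/(1-r^2))` on n-2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `r`, `p`, `n`; `r` is `NA` (with a message in
#'   `note`) when either vector is constant.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  n <- length(x)
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    return(list(r = NA_real_, p = NA_real_, n = n,
                note = "undefined for a constant vector"))
  rx <- rank(x); ry <- rank(y)
  r <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  if (abs(r) >= 1) return(list(r = r, p = 0, n = n))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tstat), df = n - 2), n = n)
}

#' Simulate the antiviral response of every patient in a cohort
#'
#' @param pars calibrated `ifndyn_parset`.
#' @param patients data.frame from [sample_cohort()].
#' @param stim_dose,ligand,variant,grid_by see [antiviral_response()].
#' @return the `patients` data.frame with columns `absolute` and `relative`
#'   appended.
#' @export
cohort_responses <- function(pars, patients, stim_dose = 608,
                             ligand = "Roferon",
                             variant = "SOCS1_or_SOCS1xUSP18",
                             grid_by = 0.05) {
  res <- lapply(seq_len(nrow(patients)), function(i) {
    r <- try(antiviral_response(pars, patients[i, ],
                                prestim_dose = patients$IFNa[i],
                                stim_dose = stim_dose, ligand = ligand,
                                variant = variant, grid_by = grid_by),
             silent = TRUE)
    if (inherits(r, "try-error"))
      stop("simulation failed for patient ", patients$patient[i], ": ",
           attr(r, "condition")$message)
    c(absolute = r$absolute, relative = r$relative)
  })
  cbind(patients, do.call(rbind, res))
}
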