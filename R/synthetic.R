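# Synthetic-data generators: the experimental design, log-normal immunoblot
# signals on gel layouts with multiplicative scaling factors, qRT-PCR Cq
# values, spike-in calibration curves, and cohort plasma concentrations.

#' Synthetic experimental design
#'
#' Emulates the shape of the calibration design: a dose panel, prestimulation
#' /stimulation combinations at 24 h, a USP18 knockdown and a USP18
#' overexpression arm, per-condition time grids, a blot observable panel and
#' a gels-per-target layout in which every gel shares the high-dose reference
#' condition.
#'
#' @param dose_panel prestimulation doses (pM).
#' @param times time grid (h) of the time-course conditions.
#' @param observables blot observable panel.
#' @param gels_per_target number of gels carrying each target.
#' @param knockdown_factor factor of the knockdown arm.
#' @return list with `conditions` (named list of [condition()]), `times`,
#'   `observables`, `gels_per_target`, `reference_condition`.
#' @export
synthetic_design <- function(dose_panel = c(0, 0.28, 2.8, 8.4, 28, 140, 280,
                                            1400, 2800),
                             times = c(0, 0.5, 1, 2, 4, 8, 12, 24),
                             observables = c("pSTAT1_Cyt", "pSTAT2_Cyt",
                                             "pSTAT1_Nuc", "pSTAT2_Nuc",
                                             "tSTAT1_Cyt", "tSTAT2_Cyt",
                                             "IRF9_Cyt", "USP18", "SOCS1",
                                             "SOCS3"),
                             gels_per_target = 3,
                             knockdown_factor = 0.05) {
  conds <- list()
  for (d in dose_panel)
    conds[[sprintf("dose_%g", d)]] <- condition(prestim_dose = d)
  conds[["pre2.8_stim1400"]] <- condition(2.8, 1400)
  conds[["pre1400_stim1400"]] <- condition(1400, 1400)
  conds[["kd_1400"]] <- condition(1400, knockdown_factor = knockdown_factor)
  conds[["oe_1400"]] <- condition(1400, overexpression = TRUE)
  list(conditions = conds, times = times, observables = observables,
       gels_per_target = gels_per_target,
       reference_condition = "dose_1400")
}

# noiseless observable table over the design
.design_truth <- function(design, truth, variant = "SOCS1_or_SOCS1xUSP18") {
  out <- list()
  for (cn in names(design$conditions)) {
    cond <- design$conditions[[cn]]
    tg <- sort(unique(c(design$times, cond$stim_time)))
    tr <- simulate_model(truth, cond, t_grid = tg, variant = variant,
                         rtol = 1e-8, atol = 1e-8)
    ob <- compute_observables(tr, truth, design$observables)
    keep <- ob[, "time"] %in% design$times
    for (o in design$observables)
      out[[length(out) + 1]] <- data.frame(
        observable = o, condition = cn, time = ob[keep, "time"],
        value = ob[keep, o])
  }
  do.call(rbind, out)
}

#' Generate synthetic immunoblot measurements
#'
#' Each target is measured on `gels_per_target` gels; every gel carries the
#' reference condition (connecting the scaling graph) plus a share of the
#' remaining conditions. Signals are the noiseless model observables times a
#' log-normal gel scaling factor times log-normal measurement noise.
#'
#' @param design from [synthetic_design()].
#' @param truth `ifndyn_parset` generator truth (e.g.
#'   [nominal_parameters()]).
#' @param noise_sd_log standard deviation of the log-scale noise
#'   (default 0.2).
#' @param gel_sd_log log-scale SD of the gel factors around 1 (default 0.5).
#' @param seed RNG seed.
#' @param variant receptor variant the data are generated under.
#' @return list with `measurements` (data.frame target, gel, condition, time,
#'   signal), `gel_factors` (the true factors), `truth_table` (noiseless
#'   observable values).
#' @export
generate_blots <- function(design, truth, noise_sd_log = 0.2,
                           gel_sd_log = 0.5, seed = 1L,
                           variant = "SOCS1_or_SOCS1xUSP18") {
  stopifnot(noise_sd_log >= 0)
  tt <- .design_truth(design, truth, variant)
  set.seed(seed)
  meas <- list(); gf <- list()
  conds <- names(design$conditions)
  nonref <- setdiff(conds, design$reference_condition)
  for (o in design$observables) {
    ng <- design$gels_per_target
    fac <- exp(rnorm(ng, 0, gel_sd_log)); fac[1] <- 1
    split_idx <- rep(seq_len(ng), length.out = length(nonref))
    for (g in seq_len(ng)) {
      gel_conds <- c(design$reference_condition, nonref[split_idx == g])
      d <- tt[tt$observable == o & tt$condition %in% gel_conds, ]
      sig <- fac[g] * pmax(d$value, 1e-12) *
        exp(rnorm(nrow(d), 0, noise_sd_log))
      meas[[length(meas) + 1]] <- data.frame(
        target = o, gel = sprintf("%s_gel%d", o, g),
        condition = d$condition, time = d$time, signal = sig)
      gf[[length(gf) + 1]] <- data.frame(
        target = o, gel = sprintf("%s_gel%d", o, g), factor = fac[g])
    }
  }
  list(measurements = do.call(rbind, meas),
       gel_factors = do.call(rbind, gf), truth_table = tt)
}

#' Generate synthetic qRT-PCR records
#'
#' mRNA fold changes of the feedback transcripts are converted to Cq values
#' via `Cq = -log_E(expression)`, with stable reference genes (GAPDH, HPRT,
#' TBP) and normal Cq noise.
#'
#' @param design from [synthetic_design()] (mRNA readouts are generated for
#'   its conditions/times).
#' @param truth generator truth.
#' @param genes transcripts to report.
#' @param noise_sd_cq Cq noise SD (default 0.3 cycles).
#' @param efficiency amplification efficiency (default 2).
#' @param seed RNG seed.
#' @param variant receptor variant.
#' @return list with `records` (gene, condition, time, Cq, efficiency) and
#'   `truth_table` (noiseless expression on the copies-per-cell scale).
#' @export
generate_qpcr <- function(design, truth,
                          genes = c("STAT1mRNA", "STAT2mRNA", "IRF9mRNA",
                                    "USP18mRNA", "SOCS1mRNA", "SOCS3mRNA"),
                          noise_sd_cq = 0.3, efficiency = 2, seed = 1L,
                          variant = "SOCS1_or_SOCS1xUSP18") {
  d2 <- design; d2$observables <- genes
  tt <- .design_truth(d2, truth, variant)
  set.seed(seed)
  # anchor expression units so target Cq values land in a realistic range
  unit <- 1e9
  recs <- data.frame(gene = tt$observable, condition = tt$condition,
                     time = tt$time,
                     Cq = -log(pmax(tt$value, 1e-6) / unit,
                               base = efficiency) +
                       rnorm(nrow(tt), 0, noise_sd_cq),
                     efficiency = efficiency)
  refs <- merge(data.frame(gene = c("GAPDH", "HPRT", "TBP")),
                unique(tt[, c("condition", "time")]))
  refs$Cq <- c(GAPDH = 18, HPRT = 26, TBP = 27)[as.character(refs$gene)] +
    rnorm(nrow(refs), 0, noise_sd_cq)
  refs$efficiency <- efficiency
  list(records = rbind(recs, refs[, names(recs)]), truth_table = tt)
}

#' Generate a synthetic spike-in calibration curve
#'
#' @param true_abundance molecules per cell of the endogenous protein.
#' @param cells_per_lysate cells lysed.
#' @param spikes calibrator amounts (molecules); defaults to a 2-fold series
#'   bracketing the endogenous amount.
#' @param noise_sd_log log-normal signal noise SD.
#' @param signal_per_molecule detection gain (arbitrary units/molecule).
#' @param n_samples replicate endogenous lysates.
#' @param seed RNG seed.
#' @return list with `amounts`, `signals`, `endogenous_signal`,
#'   `cells_per_lysate`, `true_abundance`.
#' @export
generate_calibration <- function(true_abundance, cells_per_lysate = 1e6,
                                 spikes = NULL, noise_sd_log = 0.1,
                                 signal_per_molecule = 1e-4, n_samples = 3,
                                 seed = 1L) {
  set.seed(seed)
  endo_molecules <- true_abundance * cells_per_lysate
  if (is.null(spikes))
    spikes <- endo_molecules * 2^seq(-3, 3)
  signals <- signal_per_molecule * spikes * exp(rnorm(length(spikes), 0,
                                                      noise_sd_log))
  endo <- signal_per_molecule * endo_molecules *
    exp(rnorm(n_samples, 0, noise_sd_log))
  list(amounts = spikes, signals = signals, endogenous_signal = endo,
       cells_per_lysate = cells_per_lysate, true_abundance = true_abundance)
}

#' Generate cohort plasma interferon concentrations
#'
#' Draws from the moment-matched log-normal of the printed plasma statistics.
#'
#' @param n number of patients.
#' @param mean,sd natural-scale moments (defaults: 0.0440 and 0.0362 pM).
#' @param seed RNG seed.
#' @return numeric vector of concentrations (pM).
#' @export
generate_cohort_plasma <- function(n, mean = 0.0440, sd = 0.0362, seed = 1L) {
  mm <- lognormal_moments(mean, sd)
  set.seed(seed)
  stats::rlnorm(n, mm$meanlog, mm$sdlog)
}

#' Cell-type ratio truths of the transfer scenarios
#'
#' The two synthetic transfer scenarios: a hepatoma-like cell line differing
#' from the control in 2 ratio parameters (induced STAT1-mRNA synthesis and
#' the lumped STAT1/STAT2 phosphorylation-association rate), and a primary-
#' hepatocyte-like system differing in 5 (receptor abundance, induced
#' STAT2-mRNA synthesis, STAT2 translation, SOCS1-mRNA degradation, nuclear
#' ISGF3 dissociation).
#'
#' @param scenario `"HepG2"` or `"PHH"`.
#' @return named numeric vector of nonzero log10 ratios.
#' @export
celltype_truth <- function(scenario = c("HepG2", "PHH")) {
  scenario <- match.arg(scenario)
  if (scenario == "HepG2")
    c(synthSTAT1mRNA = 0.5, actSTAT12 = -0.5)
  else
    c(Rec0 = -0.4, synthSTAT2mRNA = 0.5, synthSTAT2 = -0.4,
      degSOCS1mRNA = 0.4, dissISGF3 = 0.5)
}
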