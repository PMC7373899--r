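# Nominal ground-truth parameterization of the synthetic-data generator.
#
# The values below were calibrated (multi-objective quasi-Newton/Nelder-Mead
# fitting, documented in the methods vignette) so that the model reproduces
# the anchor behaviour the generator must emulate:
#   * 1-h nuclear phospho-STAT dose-response: pSTAT1 at 50% of its maximum at
#     2.8 pM and >= 99% at 1,400 pM; pSTAT2 at 10% of maximum at 2.8 pM
#     (dose-response curves saturating monotonically by 1,400 pM);
#   * cytoplasmic phospho-STAT transients peaking well inside the first hour
#     of a 1,400 pM dose;
#   * hypersensitization of the 24-28 h antiviral response after low-dose
#     prestimulation (~0.3-5 pM) and desensitization above ~10 pM, with
#     strong desensitization at 608 pM Roferon / 1,400 pM IFNa;
#   * a USP18 protein knockdown of > 96% reachable by scaling USP18 mRNA
#     synthesis, so the printed 94.5% knockdown efficiency is attainable by
#     root-finding.
# Abundances sit in the printed ranges (STAT1 1e5-1e6, STAT2 1e4-1e5
# molecules per cell); rates are 1/h.

#' Nominal ground-truth parameter set of the synthetic-data generator
#'
#' Returns the calibrated generator truth and verifies its printed
#' dose-response anchors by simulation: the 1-h nuclear pSTAT1 response at
#' 2.8 pM must be 50% +/- `tol` of the response at 2,800 pM, and the nuclear
#' pSTAT2 response 10% +/- `tol`. Generation fails loudly if an anchor is
#' missed. The achieved anchor matrix and the cytoplasmic phospho peak times
#' at 1,400 pM (0.1-h grid argmax) are attached as attributes `anchors` and
#' `peak_times`.
#'
#' @param seed integer recorded for reproducibility; the verification is
#'   deterministic and seed-independent.
#' @param tol maximal acceptable absolute anchor residual (default 0.05).
#' @param verify set `FALSE` to skip the simulation-based anchor check.
#' @return an `ifndyn_parset`.
#' @export
nominal_parameters <- function(seed = 1L, tol = 0.05, verify = TRUE) {
  key <- sprintf("s%d_%s", seed, verify)
  if (!is.null(.nominal_cache[[key]])) return(.nominal_cache[[key]])
  out <- base_parameters()
  if (verify) {
    rel <- .dose_response_1h(out, .anchor_doses)
    resid <- abs(rel[, 1] - .anchor_target[, 1])
    if (max(resid) > tol)
      stop(sprintf("nominal anchor check failed: max residual %.3f > %.3f",
                   max(resid), tol))
    attr(out, "anchors") <- rel
    attr(out, "peak_times") <- c(pSTAT1_Cyt = .peak_time(out, "pSTAT1_Cyt"),
                                 pSTAT2_Cyt = .peak_time(out, "pSTAT2_Cyt"))
  }
  .nominal_cache[[key]] <- out
  out
}

#' Calibrated base parameter values of the generator truth
#'
#' The raw parameter values underlying [nominal_parameters()], without the
#' anchor verification. See the methods vignette for how each block was
#' chosen.
#' @return an `ifndyn_parset`.
#' @export
base_parameters <- function() {
  dynamic <- log10(c(
    # receptor: fast resupply, deactivation/recycling, feedback-mediated
    # degradation of the active complex (SOCS1 route weak, SOCS1:USP18
    # cooperative route strong -- engages only once USP18 accumulates)
    BindIFN = 2.244e-1, degRec = 0.2, recycRec = 4.241,
    KiSOCS = 300, VdegSOCS1 = 0.8, KmdegSOCS1 = 200,
    VdegCoop = 40, KmdegCoop = 5e3,
    # lumped phosphorylation/dimerization with competitive receptor docking
    actSTAT1 = 5.366e-7, actSTAT12 = 2e-8,
    KmactSTAT1 = 6.765e3, KmactSTAT2 = 9.993e6,
    KiUSP18 = 1e4, formISGF3 = 1e-4,
    impComplex = 3, impMono = 0.05, impIRF9 = 0.1, expMono = 0.2,
    dissSTAT = 0.78, dissISGF3 = 0.3,
    bindGAS = 3, KmGAS = 3e4, offGAS = 1.5,
    bindISREhet = 1.132e-1, bindISREisgf3 = 7.605, KmISRE = 1.467e3,
    offISRE = 6.385e-1,
    degSTAT1 = 0.02, degSTAT2 = 0.03, degIRF9 = 0.05,
    synthSTAT1mRNA = 40, synthSTAT2mRNA = 400, synthIRF9mRNA = 400,
    synthIRF2mRNA = 30, synthUSP18mRNA = 5.925e2, synthSOCS1mRNA = 30,
    synthSOCS3mRNA = 2e3,
    KiIRF2 = 1e3,
    degSTAT1mRNA = 0.15, degSTAT2mRNA = 0.15, degIRF9mRNA = 0.2,
    degIRF2mRNA = 0.8, degUSP18mRNA = 1, degSOCS1mRNA = 1.2,
    degSOCS3mRNA = 3,
    synthSTAT1 = 20, synthSTAT2 = 1, synthIRF9 = 1, synthIRF2 = 2,
    synthUSP18 = 2.464e-1, synthSOCS1 = 2, synthSOCS3 = 5,
    synthUSP18mRNAbasal_OE = 50, synthUSP18_inh = 1,
    synthUSP18mRNAbasal_inh = 1, synthUSP18mRNA_inh = 1))
  initials <- log10(c(
    Rec0 = 2e3, totSTAT1 = 4e5, totSTAT2 = 5e4, totIRF9 = 8e3,
    USP18_0 = 100, SOCS1_0 = 20, SOCS3_0 = 200, IRF2_0 = 500,
    USP18mRNA_0 = 15, SOCS1mRNA_0 = 4, SOCS3mRNA_0 = 30, IRF2mRNA_0 = 20))
  scalings <- setNames(rep(0, length(.scaling_names)), .scaling_names)
  scalings[grep("^offset_", .scaling_names)] <- -6
  parset(dynamic, initials, scalings)
}

# 1-h nuclear phospho dose-response above baseline, relative to the response
# at the top dose; rows pSTAT1, pSTAT2
.dose_response_1h <- function(pars, doses, variant = "SOCS1_or_SOCS1xUSP18") {
  resp <- vapply(c(0, doses), function(d) {
    tr <- simulate_model(pars, condition(prestim_dose = d),
                         t_grid = c(0, 1), variant = variant,
                         rtol = 1e-8, atol = 1e-8)
    ob <- compute_observables(tr, pars, c("pSTAT1_Nuc", "pSTAT2_Nuc"))
    ob[2, c("pSTAT1_Nuc", "pSTAT2_Nuc")]
  }, numeric(2))
  r <- sweep(resp[, -1, drop = FALSE], 1, resp[, 1], `-`)
  rel <- sweep(r, 1, r[, ncol(r)], `/`)
  rownames(rel) <- c("pSTAT1", "pSTAT2")
  colnames(rel) <- as.character(doses)
  rel
}

.anchor_doses <- c(2.8, 28, 1400, 2800)
.anchor_target <- rbind(pSTAT1 = c(0.50, 0.90, 1.00, 1.00),
                        pSTAT2 = c(0.10, 0.80, 1.00, 1.00))

.peak_time <- function(pars, obs, dose = 1400, tmax = 3, by = 0.1) {
  tr <- simulate_model(pars, condition(prestim_dose = dose),
                       t_grid = seq(0, tmax, by), rtol = 1e-8, atol = 1e-8)
  ob <- compute_observables(tr, pars, obs)
  unname(ob[which.max(ob[, obs]), "time"])
}

.nominal_cache <- new.env(parent = emptyenv())
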