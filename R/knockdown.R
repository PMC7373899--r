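# Calibration of the siRNA knockdown factor against a target protein-level
# knockdown efficiency.

#' Calibrate the USP18 knockdown factor to a target efficiency
#'
#' Finds, by bisection, the multiplicative USP18-mRNA-synthesis scale whose
#' simulated USP18 protein level at `at_time` under `dose` pM stimulation is
#' reduced by `target_reduction` relative to the unperturbed simulation, and
#' reports the achieved reduction.
#'
#' @param pars `ifndyn_parset`.
#' @param target_reduction fractional protein reduction aimed for (default
#'   0.945, the measured knockdown efficiency at 24 h of 1,400 pM).
#' @param dose stimulation dose in pM at t = 0 (default 1400).
#' @param at_time evaluation time in hours (default 24).
#' @param variant receptor variant.
#' @param tol bisection tolerance on the achieved reduction.
#' @return list with `knockdown_factor`, `achieved_reduction`,
#'   `usp18_control`, `usp18_knockdown`.
#' @export
calibrate_knockdown <- function(pars, target_reduction = 0.945, dose = 1400,
                                at_time = 24,
                                variant = "SOCS1_or_SOCS1xUSP18",
                                tol = 1e-4) {
  usp18_at <- function(kd) {
    tr <- simulate_model(pars, condition(prestim_dose = dose,
                                         knockdown_factor = kd),
                         t_grid = c(0, at_time), variant = variant,
                         rtol = 1e-8, atol = 1e-10)
    tr[2, "USP18"]
  }
  ctrl <- usp18_at(1)
  redf <- function(kd) 1 - usp18_at(kd) / ctrl
  if (redf(0) < target_reduction)
    stop(sprintf("target reduction %.3f unreachable (max %.3f)",
                 target_reduction, redf(0)))
  lo <- 0; hi <- 1    # reduction decreases monotonically in the factor
  while (TRUE) {
    mid <- (lo + hi) / 2
    r <- redf(mid)
    if (abs(r - target_reduction) < tol) break
    if (r > target_reduction) lo <- mid else hi <- mid
    if (hi - lo < 1e-12) break
  }
  list(knockdown_factor = mid, achieved_reduction = unname(r),
       usp18_control = ctrl, usp18_knockdown = usp18_at(mid))
}
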