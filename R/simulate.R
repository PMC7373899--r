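# Simulation of experimental conditions: dosing events are discontinuous
# additions to the clamped ligand input, handled by stopping and restarting
# the stiff integrator at every event time.

#' Define an experimental condition
#'
#' @param prestim_dose ligand dose (pM) applied at t = 0.
#' @param stim_dose ligand dose (pM) added at `stim_time`.
#' @param stim_time stimulation time in hours (default 24).
#' @param ligand `"IFNa"` or `"Roferon"`. Roferon acts through the same
#'   receptor with a fixed potency factor 1400/608 relative to IFNa (the
#'   printed equipotent dose pair).
#' @param washout optional numeric vector of two increasing times
#'   `c(remove, readd)`: ligand removed at the first, restored at the second.
#' @param knockdown_factor multiplicative scale in `[0, 1]` applied to USP18
#'   mRNA synthesis (siRNA knockdown); 1 = unperturbed.
#' @param overexpression logical; activates the constitutive USP18
#'   transcription term (`synthUSP18mRNAbasal_OE`) from t = 0.
#' @param ratio_vector optional named log10 ratios added to eligible
#'   parameters (cell-type transfer).
#' @param abundance_overrides optional named molecules/cell values for
#'   `STAT1`, `STAT2`, `IRF9`, `USP18` (patient-specific abundances).
#' @param name optional condition identifier.
#' @return object of class `ifndyn_condition`.
#' @export
condition <- function(prestim_dose = 0, stim_dose = 0, stim_time = 24,
                      ligand = c("IFNa", "Roferon"), washout = NULL,
                      knockdown_factor = 1, overexpression = FALSE,
                      ratio_vector = NULL, abundance_overrides = NULL,
                      name = NULL) {
  ligand <- match.arg(ligand)
  stopifnot(prestim_dose >= 0, stim_dose >= 0,
            knockdown_factor >= 0, knockdown_factor <= 1)
  if (!is.null(washout)) {
    stopifnot(length(washout) == 2, all(diff(washout) > 0))
  }
  structure(list(prestim_dose = prestim_dose, stim_dose = stim_dose,
                 stim_time = stim_time, ligand = ligand, washout = washout,
                 knockdown_factor = knockdown_factor,
                 overexpression = overexpression,
                 ratio_vector = ratio_vector,
                 abundance_overrides = abundance_overrides,
                 name = name %||% sprintf("pre%g_stim%g", prestim_dose,
                                          stim_dose)),
            class = "ifndyn_condition")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.roferon_potency <- 1400 / 608

# apply condition-level parameter modifications (ratios, abundance overrides)
.condition_pars <- function(pars, cond) {
  x <- unclass(pars)
  if (!is.null(cond$ratio_vector)) {
    nm <- names(cond$ratio_vector)
    if (!all(nm %in% names(x))) stop("unknown ratio parameter(s): ",
                                     paste(setdiff(nm, names(x)), collapse = ", "))
    x[nm] <- x[nm] + cond$ratio_vector
  }
  ab <- cond$abundance_overrides
  if (!is.null(ab)) {
    map <- c(STAT1 = "totSTAT1", STAT2 = "totSTAT2", IRF9 = "totIRF9",
             USP18 = "USP18_0")
    nm <- names(ab)
    if (!all(nm %in% names(map))) stop("abundance overrides allowed for ",
                                       "STAT1, STAT2, IRF9, USP18 only")
    if (any(ab <= 0)) stop("abundance overrides must be positive")
    if ("USP18" %in% nm) {
      # a patient's USP18 abundance is an expression scale: basal mRNA and
      # induced transcription capacity move with the protein level, so the
      # derived protein turnover and the translation delay stay invariant
      f <- log10(ab[["USP18"]]) - x[["USP18_0"]]
      x["USP18mRNA_0"] <- x["USP18mRNA_0"] + f
      x["synthUSP18mRNA"] <- x["synthUSP18mRNA"] + f
    }
    x[map[nm]] <- log10(ab)
  }
  structure(x, class = "ifndyn_parset")
}

# event schedule: times and the ligand level (IFNa-equivalent pM) from each
.dose_schedule <- function(cond) {
  pot <- if (cond$ligand == "Roferon") .roferon_potency else 1
  lev0 <- cond$prestim_dose * pot
  times <- 0
  levels <- lev0
  if (!is.null(cond$washout)) {
    times <- c(times, cond$washout[1]); levels <- c(levels, 0)
    times <- c(times, cond$washout[2]); levels <- c(levels, lev0)
  }
  if (cond$stim_dose > 0) {
    times <- c(times, cond$stim_time)
    levels <- c(levels, levels[length(levels)] + cond$stim_dose * pot)
  }
  ord <- order(times)
  list(times = times[ord], levels = levels[ord])
}

#' Simulate the model under an experimental condition
#'
#' The parameter set is steady-state transformed (after applying any
#' condition-level ratio vector or abundance overrides), the system starts in
#' the unstimulated steady state at t = 0, and the ligand input is a
#' piecewise-constant clamped dose changed only at event times, where the
#' integrator is stopped and restarted.
#'
#' @param pars an `ifndyn_parset`.
#' @param cond an [condition()] object.
#' @param t_grid output time grid in hours (must start at >= 0).
#' @param variant receptor variant (see [build_network()]).
#' @param rtol,atol solver tolerances (lsoda).
#' @param init_state optional named state vector overriding the steady-state
#'   initial condition (advanced use: restarting from a stored state).
#' @return object of class `ifndyn_traj`: numeric matrix (time points x
#'   1+41), first column `time`, with the condition attached as attribute.
#' @export
simulate_model <- function(pars, cond = condition(), t_grid = seq(0, 24, 0.1),
                           variant = "SOCS1_or_SOCS1xUSP18",
                           rtol = 1e-8, atol = 1e-10, init_state = NULL) {
  if (!variant %in% .variants) stop("unknown receptor variant: ", variant)
  stopifnot(!is.unsorted(t_grid), t_grid[1] >= 0)
  pars2 <- .condition_pars(pars, cond)
  ss <- apply_steady_state(pars2)
  p <- .c_parms(ss, variant, cond$knockdown_factor, cond$overexpression)

  sched <- .dose_schedule(cond)
  if (max(sched$times) > max(t_grid))
    stop("t_grid must cover all event times")
  bounds <- c(sched$times, max(t_grid))
  y <- if (is.null(init_state)) ss$y0 else init_state[.state_names]
  out <- NULL
  for (k in seq_along(sched$times)) {
    p["IFN"] <- sched$levels[k]
    t0 <- bounds[k]; t1 <- bounds[k + 1]
    if (t1 <= t0) next
    seg_times <- sort(unique(c(t0, t_grid[t_grid > t0 & t_grid <= t1], t1)))
    sol <- deSolve::lsoda(y, seg_times, func = "ifndyn_derivs",
                          parms = p, dllname = "ifndyn",
                          initfunc = "ifndyn_initmod",
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop(sprintf("solver failure in condition '%s' near t = %.3g h",
                   cond$name, sol[nrow(sol), 1]))
    y <- sol[nrow(sol), -1]
    keep <- sol[, 1] %in% t_grid & (sol[, 1] > t0 | k == 1)
    out <- rbind(out, sol[keep, , drop = FALSE])
  }
  colnames(out) <- c("time", .state_names)
  neg <- min(out[, -1])
  if (neg < -10 * max(atol, rtol * max(abs(out[, -1]))))
    warning(sprintf("negative state beyond tolerance in condition '%s': %g",
                    cond$name, neg))
  structure(out, class = c("ifndyn_traj", "matrix"), condition = cond,
            variant = variant, ss = ss)
}

#' Unstimulated steady state reached by the transform
#' @param pars an `ifndyn_parset`.
#' @return named state vector at the unstimulated fixed point.
#' @export
steady_state_values <- function(pars) apply_steady_state(pars)$y0
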