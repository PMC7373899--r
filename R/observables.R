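# Observation model: each observable is scale * (stoichiometry-weighted sum
# of mapped states) + offset. Phospho-observables count every phosphorylated
# STAT molecule in the compartment (a homodimer carries two pSTAT1);
# total-STAT observables add the free unphosphorylated pool.

.obs_map <- local({
  m <- list(
    pSTAT1_Cyt = c(pSTAT1dimc = 2, pSTAT1pSTAT2c = 1, ISGF3c = 1),
    pSTAT1_Nuc = c(pSTAT1dimn = 2, pSTAT1pSTAT2n = 1, ISGF3n = 1),
    pSTAT2_Cyt = c(pSTAT1pSTAT2c = 1, ISGF3c = 1),
    pSTAT2_Nuc = c(pSTAT1pSTAT2n = 1, ISGF3n = 1),
    tSTAT1_Cyt = c(STAT1c = 1, pSTAT1dimc = 2, pSTAT1pSTAT2c = 1, ISGF3c = 1),
    tSTAT1_Nuc = c(STAT1n = 1, pSTAT1dimn = 2, pSTAT1pSTAT2n = 1, ISGF3n = 1),
    tSTAT2_Cyt = c(STAT2c = 1, pSTAT1pSTAT2c = 1, ISGF3c = 1),
    tSTAT2_Nuc = c(STAT2n = 1, pSTAT1pSTAT2n = 1, ISGF3n = 1),
    IRF9_Cyt = c(IRF9c = 1, ISGF3c = 1),
    IRF9_Nuc = c(IRF9n = 1, ISGF3n = 1),
    USP18 = c(USP18 = 1), SOCS1 = c(SOCS1 = 1), SOCS3 = c(SOCS3 = 1))
  # unscaled readouts: mRNAs (qRT-PCR works in fold changes), promoter
  # occupancy, IRF2, and the total occupied-site response proxy
  for (g in .genes) m[[paste0(g, "mRNA")]] <- setNames(1, paste0(g, "mRNA"))
  m$IRF2 <- c(IRF2 = 1)
  m$OccGASbs <- c(OccGASbs = 1)
  m$OccGISREbs <- c(OccGISREbs = 1)
  m$OccSites <- c(OccGASbs = 1, OccGISREbs = 1)
  m
})

.scaled_obs <- c("pSTAT1_Cyt", "pSTAT2_Cyt", "pSTAT1_Nuc", "pSTAT2_Nuc",
                 "tSTAT1_Cyt", "tSTAT1_Nuc", "tSTAT2_Cyt", "tSTAT2_Nuc",
                 "IRF9_Cyt", "IRF9_Nuc", "USP18", "SOCS1", "SOCS3")
.offset_obs <- c("pSTAT1_Cyt", "pSTAT2_Cyt", "pSTAT1_Nuc", "pSTAT2_Nuc")

#' Names of all defined observables
#' @return character vector.
#' @export
observable_names <- function() names(.obs_map)

#' Compute observable time courses from a trajectory
#'
#' @param traj an `ifndyn_traj` from [simulate_model()].
#' @param pars the `ifndyn_parset` used for the simulation (supplies the
#'   observation scalings/offsets).
#' @param observables character vector of observable names
#'   (see [observable_names()]).
#' @return numeric matrix (time points x 1+observables), first column `time`.
#' @export
compute_observables <- function(traj, pars,
                                observables = observable_names()) {
  bad <- setdiff(observables, names(.obs_map))
  if (length(bad)) stop("unmapped observable(s): ", paste(bad, collapse = ", "))
  nat <- natural_scale(pars)
  states <- unclass(traj)[, -1, drop = FALSE]
  out <- matrix(NA_real_, nrow(states), length(observables),
                dimnames = list(NULL, observables))
  for (ob in observables) {
    w <- .obs_map[[ob]]
    val <- as.vector(states[, names(w), drop = FALSE] %*% w)
    if (ob %in% .scaled_obs) val <- nat[[paste0("scale_", ob)]] * val
    if (ob %in% .offset_obs) val <- val + nat[[paste0("offset_", ob)]]
    out[, ob] <- val
  }
  cbind(time = unclass(traj)[, 1], out)
}
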