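# Scaled-down in-silico studies: receptor-variant selection by BIC and
# cell-type transfer by elastic net, run end-to-end on synthetic data from
# the nominal generator truth. These are the workhorses of the acceptance
# checks; problem sizes (conditions, time points, starts) are chosen so a
# study completes in about a minute on one core.

# noisy observable dataset over a list of conditions
.study_data <- function(truth, conds, times, obs, noise, seed,
                        variant = "SOCS1_or_SOCS1xUSP18") {
  set.seed(seed)
  out <- list()
  for (cn in names(conds)) {
    tt <- if (conds[[cn]]$stim_dose > 0) c(times, 25, 26, 28) else times
    tg <- sort(unique(c(0, tt, conds[[cn]]$stim_time)))
    tr <- simulate_model(truth, conds[[cn]], t_grid = tg, variant = variant)
    ob <- compute_observables(tr, truth, obs)
    rows <- match(tt, ob[, "time"])
    for (o in obs) {
      v <- ob[rows, o]
      out[[length(out) + 1]] <- data.frame(
        observable = o, condition = cn, time = tt,
        estimate = v * exp(rnorm(length(v), 0, noise)),
        sigma = pmax(abs(v) * noise, 1e-4))
    }
  }
  do.call(rbind, out)
}

#' Receptor-variant selection study
#'
#' Generates a synthetic dataset under the SOCS1 | SOCS1:USP18 truth
#' (control, USP18-knockdown, USP18-overexpression and prestimulation/
#' stimulation conditions), fits all four receptor-degradation variants by
#' multi-start maximum likelihood (the superset variant additionally receives
#' hierarchical starts assembled from the sub-model optima), and ranks the
#' variants by BIC.
#'
#' @param seed seed for data noise and optimization starts.
#' @param noise log-scale measurement noise SD (default 0.03).
#' @param n_starts multi-starts per variant.
#' @return list with `comparison` (from [compare_models()]), `winner`,
#'   `n_data`, `fits`.
#' @export
variant_selection_study <- function(seed = 11L, noise = 0.03, n_starts = 16) {
  truth <- nominal_parameters()
  conds <- list(
    tc1400 = condition(prestim_dose = 1400),
    kd1400 = condition(prestim_dose = 1400, knockdown_factor = 0.05),
    oe1400 = condition(prestim_dose = 1400, overexpression = TRUE),
    pp = condition(prestim_dose = 1400, stim_dose = 1400))
  times <- c(0.5, 1, 2, 4, 8, 12, 24)
  obs <- c("pSTAT1_Cyt", "pSTAT2_Cyt", "USP18", "tSTAT2_Cyt")
  data <- .study_data(truth, conds, times, obs, noise, seed)

  common <- c("KiUSP18", "recycRec")
  free_of <- list(
    SOCS1 = c("VdegSOCS1", "KmdegSOCS1", common),
    USP18 = c("VdegSOCS1", "KmdegSOCS1", common),
    SOCS1xUSP18 = c("VdegCoop", "KmdegCoop", common),
    SOCS1_or_SOCS1xUSP18 = c("VdegSOCS1", "KmdegSOCS1", "VdegCoop",
                             "KmdegCoop", common))
  fits <- list(); best_pars <- list()
  for (v in c("SOCS1", "USP18", "SOCS1xUSP18")) {
    free <- free_of[[v]]
    obj <- make_objective(data, truth, free, conds, variant = v)
    box <- rbind(unclass(truth)[free] - 1.5, unclass(truth)[free] + 1.5)
    colnames(box) <- free
    ms <- multistart(obj, n_starts = n_starts, start_box = box,
                     seed = seed + 10)
    fits[[v]] <- list(objective = ms$best$objective, k = length(free))
    best_pars[[v]] <- ms$best$par
  }
  free <- free_of$SOCS1_or_SOCS1xUSP18
  obj <- make_objective(data, truth, free, conds,
                        variant = "SOCS1_or_SOCS1xUSP18")
  box <- rbind(unclass(truth)[free] - 1.5, unclass(truth)[free] + 1.5)
  colnames(box) <- free
  inc <- rbind(
    c(best_pars$SOCS1[c("VdegSOCS1", "KmdegSOCS1")],
      unclass(truth)[c("VdegCoop", "KmdegCoop")], best_pars$SOCS1[common]),
    c(unclass(truth)[c("VdegSOCS1", "KmdegSOCS1")],
      best_pars$SOCS1xUSP18[c("VdegCoop", "KmdegCoop")],
      best_pars$SOCS1xUSP18[common]))
  colnames(inc) <- free
  ms <- multistart(obj, n_starts = n_starts, start_box = box,
                   seed = seed + 10, include = inc)
  fits$SOCS1_or_SOCS1xUSP18 <- list(objective = ms$best$objective,
                                    k = length(free))
  cmp <- compare_models(fits, n_data = nrow(data))
  list(comparison = cmp, winner = attr(cmp, "winner"), n_data = nrow(data),
       fits = fits)
}

#' Cell-type transfer study (elastic-net ratio recovery)
#'
#' Generates synthetic data under the control model with the scenario's true
#' log10 ratios applied ([celltype_truth()]), fits the regularization path
#' over a scaled-down candidate ratio set, and selects the cell-type model by
#' the modified information criterion.
#'
#' @param scenario `"HepG2"` (2 true ratios) or `"PHH"` (5 true ratios).
#' @param seed seed for data noise and path starts.
#' @param noise log-scale measurement noise SD.
#' @param lam_grid regularization strengths of the scaled-down path.
#' @param n_starts random starts per lambda (the zero vector and the warm
#'   start are always added).
#' @return list with `selection` (from [select_celltype_model()]), `selected`
#'   (names), `true` (names), `k`, `path`, `candidates` (the ratio parameter
#'   names of the candidate set).
#' @export
celltype_transfer_study <- function(scenario = c("HepG2", "PHH"), seed = 31L,
                                    noise = 0.05,
                                    lam_grid = c(50, 150, 400, 800, 1600),
                                    n_starts = 3) {
  scenario <- match.arg(scenario)
  control <- nominal_parameters()
  cands <- c("synthSTAT1mRNA", "actSTAT12", "Rec0", "synthSTAT2mRNA",
             "synthSTAT2", "degSOCS1mRNA", "dissISGF3", "KiUSP18",
             "impComplex", "degSTAT1mRNA")
  delta_true <- celltype_truth(scenario)
  stopifnot(all(names(delta_true) %in% cands))
  conds <- list(tc28 = condition(prestim_dose = 28),
                tc1400 = condition(prestim_dose = 1400),
                pp = condition(prestim_dose = 2.8, stim_dose = 1400))
  times <- c(0.5, 1, 2, 4, 8, 12, 24)
  obs <- c("pSTAT1_Cyt", "pSTAT2_Cyt", "pSTAT2_Nuc", "tSTAT1_Cyt",
           "tSTAT2_Cyt", "SOCS1mRNA", "STAT2mRNA", "IRF9_Cyt")
  truth <- control
  truth[names(delta_true)] <- unclass(truth)[names(delta_true)] + delta_true
  data <- .study_data(truth, conds, times, obs, noise, seed)

  obj_abs <- make_objective(data, control, cands, conds, prior = "none")
  base <- unclass(control)[cands]
  obj_delta <- function(delta) obj_abs(base + delta)
  path <- fit_path(obj_delta, n_ratio = length(cands), lam_grid = lam_grid,
                   n_starts = n_starts, seed = seed + 10,
                   control = list(iter.max = 400))
  sel <- select_celltype_model(path, obj_delta, n_data = nrow(data))
  list(selection = sel, selected = cands[sel$nonzero],
       true = names(delta_true), k = sel$k, path = path, candidates = cands)
}
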