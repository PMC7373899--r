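p_nom <- nominal_parameters()

test_that("without ligand all species stay at the steady state", {
  y0 <- steady_state_values(p_nom)
  tr <- simulate_model(p_nom, condition(), t_grid = seq(0, 48, 12))
  for (i in 2:nrow(tr))
    expect_equal(unname(tr[i, -1]), unname(y0), tolerance = 1e-8)
})

test_that("states stay non-negative within solver tolerance", {
  for (d in c(0.28, 28, 2800)) {
    tr <- simulate_model(p_nom, condition(prestim_dose = d, stim_dose = 1400),
                         t_grid = seq(0, 28, 0.5))
    expect_gt(min(tr[, -1]), -1e-9 * max(tr[, -1]))
  }
})

test_that("STAT1 and receptor moieties are conserved when turnover is off", {
  # all synthesis and degradation rates effectively zero
  p <- base_parameters()
  off <- c("degRec", "degSTAT1", "degSTAT2", "degIRF9",
           "VdegSOCS1", "VdegCoop",
           paste0("deg", ifndyn:::.genes, "mRNA"),
           paste0("synth", ifndyn:::.genes, "mRNA"),
           paste0("synth", ifndyn:::.genes))
  p[off] <- -30
  # oracle: the moiety weights lie in the left null space of the
  # stoichiometry matrix restricted to the remaining (non-turnover) reactions
  net <- build_network()
  S <- stoichiometry_matrix(net)
  keep <- !grepl("^(synth_|deg_|transl_)", colnames(S))
  S2 <- S[, keep]
  w <- setNames(numeric(nrow(S2)), rownames(S2))
  w[c("STAT1c", "STAT1n")] <- 1
  w[c("pSTAT1dimc", "pSTAT1dimn")] <- 2
  w[c("pSTAT1pSTAT2c", "pSTAT1pSTAT2n", "ISGF3c", "ISGF3n")] <- 1
  expect_equal(max(abs(t(S2) %*% w)), 0)
  wr <- setNames(numeric(nrow(S2)), rownames(S2))
  wr[c("Rec", "aRecIFN")] <- 1
  expect_equal(max(abs(t(S2) %*% wr)), 0)

  tr <- simulate_model(p, condition(prestim_dose = 1400),
                       t_grid = seq(0, 24, 4))
  m1 <- as.matrix(unclass(tr)[, names(w)]) %*% w
  expect_lt(max(abs(m1 - m1[1])) / m1[1], 1e-8)
  mr <- as.matrix(unclass(tr)[, names(wr)]) %*% wr
  expect_lt(max(abs(mr - mr[1])) / mr[1], 1e-8)
})

test_that("stopping and restarting at the event reproduces the single call", {
  cond <- condition(prestim_dose = 2.8, stim_dose = 1400, stim_time = 24)
  g <- seq(0, 28, 0.5)
  single <- simulate_model(p_nom, cond, t_grid = g)
  first <- simulate_model(p_nom, condition(prestim_dose = 2.8),
                          t_grid = seq(0, 24, 0.5))
  state24 <- first[nrow(first), -1]
  second <- simulate_model(p_nom,
                           condition(prestim_dose = 2.8 + 1400),
                           t_grid = seq(0, 4, 0.5),
                           init_state = state24)
  got <- unclass(second)[-1, -1]
  want <- unclass(single)[single[, "time"] > 24, -1]
  expect_lt(max(abs(got - want) / pmax(abs(want), 1e-6)), 1e-6)
})

test_that("prestimulation dose reshapes the restimulation response (refractoriness)", {
  resp <- function(pre) {
    tr <- simulate_model(p_nom, condition(prestim_dose = pre,
                                          stim_dose = 1400, stim_time = 24),
                         t_grid = c(0, 24, 25))
    ob <- compute_observables(tr, p_nom, "pSTAT2_Nuc")
    ob[3, "pSTAT2_Nuc"] - ob[2, "pSTAT2_Nuc"]
  }
  unprimed <- resp(0)
  expect_lt(resp(1400), unprimed)   # high-dose priming desensitizes
  expect_gt(resp(2.8), unprimed)    # low-dose priming hypersensitizes
})

test_that("phospho-STAT transients peak within the first hour at 1,400 pM", {
  tp <- attr(p_nom, "peak_times")
  expect_true(all(tp > 0 & tp <= 0.5))
  # the trajectory rises to the peak and decays past it
  tr <- simulate_model(p_nom, condition(prestim_dose = 1400),
                       t_grid = seq(0, 3, 0.1))
  ob <- compute_observables(tr, p_nom, "pSTAT2_Cyt")
  i <- which.max(ob[, "pSTAT2_Cyt"])
  expect_equal(unname(ob[i, "time"]), tp[["pSTAT2_Cyt"]])
  expect_gt(ob[i, "pSTAT2_Cyt"], ob[nrow(ob), "pSTAT2_Cyt"])
})

test_that("Roferon doses act through the fixed potency factor", {
  t1 <- simulate_model(p_nom, condition(prestim_dose = 608,
                                        ligand = "Roferon"),
                       t_grid = c(0, 1, 4))
  t2 <- simulate_model(p_nom, condition(prestim_dose = 1400),
                       t_grid = c(0, 1, 4))
  expect_equal(unclass(t1)[, -1], unclass(t2)[, -1], tolerance = 1e-10)
})

test_that("knockdown scales USP18 synthesis and overexpression adds to it", {
  tr1 <- simulate_model(p_nom, condition(prestim_dose = 1400),
                        t_grid = c(0, 24))
  trk <- simulate_model(p_nom, condition(prestim_dose = 1400,
                                         knockdown_factor = 0.05),
                        t_grid = c(0, 24))
  tro <- simulate_model(p_nom, condition(overexpression = TRUE),
                        t_grid = c(0, 24))
  expect_lt(trk[2, "USP18"], tr1[2, "USP18"])
  expect_gt(tro[2, "USP18"], steady_state_values(p_nom)[["USP18"]])
})

test_that("washout events remove and restore the ligand", {
  cond <- condition(prestim_dose = 1400, washout = c(20.5, 24))
  tr <- simulate_model(p_nom, cond, t_grid = seq(0, 28, 0.5))
  a <- unclass(tr)[, "aRecIFN"]
  t <- tr[, "time"]
  expect_lt(a[t == 23.5], a[t == 20] / 5)   # complex decays after removal
  expect_gt(a[t == 25], a[t == 23.5] * 5)   # and reforms on re-addition
  expect_error(condition(washout = c(24, 20)))
})

test_that("observable mapping is linear in scales and additive in offsets", {
  tr <- simulate_model(p_nom, condition(prestim_dose = 1400),
                       t_grid = seq(0, 4, 1))
  ob1 <- compute_observables(tr, p_nom, c("pSTAT1_Cyt", "USP18"))
  p2 <- p_nom
  p2["scale_pSTAT1_Cyt"] <- p2["scale_pSTAT1_Cyt"] + log10(2)
  ob2 <- compute_observables(tr, p2, "pSTAT1_Cyt")
  off <- natural_scale(p_nom)[["offset_pSTAT1_Cyt"]]
  expect_equal(ob2[, "pSTAT1_Cyt"] - off,
               2 * (ob1[, "pSTAT1_Cyt"] - off), tolerance = 1e-12)
  # single-state observable with unit scale equals the state trajectory
  expect_equal(unname(compute_observables(tr, p_nom, "OccGASbs")[, 2]),
               unname(unclass(tr)[, "OccGASbs"]))
  # total-STAT observables sum the free and complexed moiety
  obt <- compute_observables(tr, p_nom, "tSTAT1_Cyt")
  manual <- unclass(tr)[, "STAT1c"] + 2 * unclass(tr)[, "pSTAT1dimc"] +
    unclass(tr)[, "pSTAT1pSTAT2c"] + unclass(tr)[, "ISGF3c"]
  expect_equal(unname(obt[, 2]),
               unname(natural_scale(p_nom)[["scale_tSTAT1_Cyt"]] * manual))
  expect_error(compute_observables(tr, p_nom, "nonexistent"), "unmapped")
})

test_that("tSTAT observables at t = 0 match the steady-state pools", {
  tr <- simulate_model(p_nom, condition(), t_grid = c(0, 1))
  ob <- compute_observables(tr, p_nom, c("tSTAT1_Cyt", "tSTAT2_Cyt"))
  y0 <- steady_state_values(p_nom)
  nat <- natural_scale(p_nom)
  expect_equal(unname(ob[1, "tSTAT1_Cyt"]),
               nat[["scale_tSTAT1_Cyt"]] * y0[["STAT1c"]])
  expect_equal(unname(ob[1, "tSTAT2_Cyt"]),
               nat[["scale_tSTAT2_Cyt"]] * y0[["STAT2c"]])
})
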