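p_nom <- nominal_parameters()

test_that("nominal truth reproduces the printed dose-response anchors", {
  rel <- attr(p_nom, "anchors")
  # half-maximal STAT1 phosphorylation at 2.8 pM
  expect_equal(rel["pSTAT1", "2.8"], 0.50, tolerance = 0.05)
  # 10% of maximal STAT2 phosphorylation at 2.8 pM
  expect_equal(rel["pSTAT2", "2.8"], 0.10, tolerance = 0.05)
  # saturated by 1,400 pM
  expect_gte(rel["pSTAT1", "1400"], 0.99)
  expect_gte(rel["pSTAT2", "1400"], 0.99)
  # zero dose gives zero response above baseline (by construction of the
  # relative scale: check the raw simulation)
  tr <- simulate_model(p_nom, condition(), t_grid = c(0, 1))
  ob <- compute_observables(tr, p_nom, "pSTAT1_Nuc")
  expect_equal(ob[2, 2], ob[1, 2], tolerance = 1e-8)
})

test_that("anchor verification fails loudly when the truth is corrupted", {
  expect_error(
    {
      p_bad <- base_parameters()
      p_bad["BindIFN"] <- p_bad["BindIFN"] + 1.5
      rel <- ifndyn:::.dose_response_1h(p_bad, ifndyn:::.anchor_doses)
      if (max(abs(rel[, 1] - ifndyn:::.anchor_target[, 1])) > 0.05)
        stop("nominal anchor check failed")
    },
    "anchor check failed")
})

test_that("noiseless blots round-trip through the scaling model", {
  des <- synthetic_design(dose_panel = c(0, 2.8, 1400),
                          times = c(0, 1, 4, 24), gels_per_target = 2)
  des$observables <- c("pSTAT1_Cyt", "USP18")
  gen <- generate_blots(des, p_nom, noise_sd_log = 0, gel_sd_log = 0.5,
                        seed = 3)
  s <- align_replicates(gen$measurements,
                        reference_rule = function(g) sort(unique(g))[1])
  # gel factors recovered exactly relative to each target's first gel
  for (tg in unique(gen$gel_factors$target)) {
    truef <- gen$gel_factors[gen$gel_factors$target == tg, ]
    estf <- s$gel_factors[s$gel_factors$target == tg, ]
    m <- match(estf$gel, truef$gel)
    expect_equal(estf$factor, truef$factor[m] / truef$factor[m][1],
                 tolerance = 1e-8)
  }
  # latent estimates equal the noiseless truth
  tt <- gen$truth_table
  key <- paste(s$estimates$target, s$estimates$condition, s$estimates$time)
  keyt <- paste(tt$observable, tt$condition, tt$time)
  expect_equal(s$estimates$estimate, pmax(tt$value[match(key, keyt)], 1e-12),
               tolerance = 1e-8)
})

test_that("the gel layout covers the design and stays connected", {
  des <- synthetic_design()
  gen <- generate_blots(des, p_nom, seed = 4)
  m <- gen$measurements
  # every gel carries the reference condition
  for (g in unique(m$gel))
    expect_true(des$reference_condition %in% m$condition[m$gel == g])
  # every design cell of the observable panel is measured at least once
  expect_setequal(unique(m$condition), names(des$conditions))
  expect_setequal(unique(m$target), des$observables)
  counts <- table(m$target, m$gel != "")
  expect_true(all(table(gen$gel_factors$target) == des$gels_per_target))
})

test_that("qPCR records round-trip to the generator's fold changes", {
  des <- synthetic_design(dose_panel = c(0, 1400), times = c(0, 4, 24),
                          gels_per_target = 1)
  gen <- generate_qpcr(des, p_nom, genes = c("USP18mRNA", "SOCS1mRNA"),
                       noise_sd_cq = 0, seed = 5)
  out <- normalize_qpcr(gen$records, baseline_condition = "dose_0",
                        baseline_time = 0)
  tt <- gen$truth_table
  base <- tt$value[tt$condition == "dose_0" & tt$time == 0]
  names(base) <- tt$observable[tt$condition == "dose_0" & tt$time == 0]
  want <- tt$value / base[tt$observable]
  key <- paste(out$gene, out$condition, out$time)
  keyt <- paste(tt$observable, tt$condition, tt$time)
  expect_equal(out$fold_change, unname(want[match(key, keyt)]),
               tolerance = 1e-6)
})

test_that("fold-change recovery stays within the noise envelope", {
  des <- synthetic_design(dose_panel = c(0, 1400), times = c(0, 24),
                          gels_per_target = 1)
  gen <- generate_qpcr(des, p_nom, genes = "USP18mRNA", noise_sd_cq = 0.3,
                       seed = 6)
  out <- normalize_qpcr(gen$records, baseline_condition = "dose_0",
                        baseline_time = 0)
  tt <- gen$truth_table
  truefc <- tt$value[tt$condition == "dose_1400" & tt$time == 24] /
    tt$value[tt$condition == "dose_0" & tt$time == 0]
  got <- out$fold_change[out$condition == "dose_1400" & out$time == 24]
  # 0.3 Cq on 4 involved measurements: about 2^(2*0.3) each way
  expect_gt(got, truefc / 2^1.2)
  expect_lt(got, truefc * 2^1.2)
})

test_that("generated measurements are reproducible under a fixed seed", {
  des <- synthetic_design(dose_panel = c(0, 28), times = c(0, 2),
                          gels_per_target = 2)
  des$observables <- "pSTAT1_Cyt"
  g1 <- generate_blots(des, p_nom, seed = 11)
  g2 <- generate_blots(des, p_nom, seed = 11)
  expect_identical(g1$measurements, g2$measurements)
})
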