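test_that("moment matching inverts the log-normal moments exactly", {
  mm <- lognormal_moments(0.0440, 0.0362)
  expect_equal(exp(mm$meanlog + mm$sdlog^2 / 2), 0.0440, tolerance = 1e-12)
  v <- (exp(mm$sdlog^2) - 1) * exp(2 * mm$meanlog + mm$sdlog^2)
  expect_equal(sqrt(v), 0.0362, tolerance = 1e-12)
  expect_error(lognormal_moments(-1, 1))
})

test_that("the study-matched cohort has 114 patients, reproducibly", {
  pat <- sample_cohort(seed = 7)
  expect_equal(nrow(pat), 114L)
  expect_true(all(pat$STAT1 > 0 & pat$IFNa > 0))
  expect_identical(pat, sample_cohort(seed = 7))   # bit-for-bit
  expect_false(identical(pat, sample_cohort(seed = 8)))
})

test_that("zero-variance configurations yield identical patients", {
  cfg <- cohort_config(n = 5)
  cfg$quantities$sd <- 0
  pat <- sample_cohort(cfg, seed = 1)
  expect_equal(pat$STAT2, rep(cfg$quantities$mean[2], 5))
})

test_that("plasma draws reproduce the configured mean (CLT check)", {
  x <- generate_cohort_plasma(10000, seed = 12)
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 0.0440), 3 * se)
})

test_that("Spearman correlation matches the rank formula and base R", {
  expect_equal(spearman(1:10, 1:10)$r, 1)
  x <- c(2.1, 0.3, 5, 1.1, 4.4)
  expect_equal(spearman(x, exp(x))$r, 1)  # monotone invariance
  # hand-computable case: squared rank differences sum to 4
  x5 <- c(1, 2, 3, 4, 5); y5 <- c(2, 1, 4, 3, 5)
  expect_equal(spearman(x5, y5)$r, 1 - 6 * 4 / (5 * 24))
  set.seed(3); a <- rnorm(25); b <- a + rnorm(25)
  expect_equal(spearman(a, b)$r, cor(a, b, method = "spearman"),
               tolerance = 1e-12)
  expect_true(is.na(spearman(rep(1, 5), 1:5)$r))
})

p_nom <- nominal_parameters()

test_that("antiviral response metrics honor their degenerate limits", {
  # no stimulation: the absolute response is exactly zero
  r0 <- antiviral_response(p_nom, prestim_dose = 2, stim_dose = 0)
  expect_identical(r0$absolute, 0)
  # no prestimulation: the relative response is exactly one
  r1 <- antiviral_response(p_nom, prestim_dose = 0)
  expect_identical(r1$relative, 1)
  expect_gt(r1$absolute, 0)
})

test_that("priming dose splits hyper- from desensitization of the response", {
  lo <- antiviral_response(p_nom, prestim_dose = 1.2, grid_by = 0.1)
  hi <- antiviral_response(p_nom, prestim_dose = 608, grid_by = 0.1)
  expect_gt(lo$relative, 1)
  expect_lt(hi$relative, 1)
})

test_that("the desensitization threshold agrees with a dense dose grid", {
  th <- desensitization_threshold(p_nom, dose_range = c(0.5, 200),
                                  grid_by = 0.1, n_scan = 7)
  expect_true(th$converged)
  # dense-grid oracle around the reported threshold
  doses <- th$threshold * 10^seq(-0.15, 0.15, length.out = 9)
  rel <- vapply(doses, function(d)
    antiviral_response(p_nom, prestim_dose = d, grid_by = 0.1)$relative, 0)
  below <- doses[rel >= 1]; above <- doses[rel < 1]
  expect_gte(th$threshold, max(below) * 0.9)
  expect_lte(th$threshold, min(above) * 1.1)
})

test_that("a range without a crossing reports no threshold", {
  th <- desensitization_threshold(p_nom, dose_range = c(100, 600),
                                  grid_by = 0.2, n_scan = 4)
  expect_false(th$converged)
  expect_true(is.na(th$threshold))
})

test_that("raising basal USP18 lowers the desensitization threshold", {
  pat_lo <- data.frame(STAT1 = 4e5, STAT2 = 5e4, IRF9 = 8e3, USP18 = 100)
  pat_hi <- transform(pat_lo, USP18 = 1000)
  th_lo <- desensitization_threshold(p_nom, pat_lo, dose_range = c(0.5, 200),
                                     grid_by = 0.1, n_scan = 6)
  th_hi <- desensitization_threshold(p_nom, pat_hi, dose_range = c(0.05, 200),
                                     grid_by = 0.1, n_scan = 7)
  expect_true(th_lo$converged && th_hi$converged)
  expect_lt(th_hi$threshold, th_lo$threshold)
})
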