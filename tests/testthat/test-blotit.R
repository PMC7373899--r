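test_that("a single gel needs no scaling and returns the measurements", {
  m <- data.frame(target = "X", gel = "g1",
                  condition = c("a", "b", "c"), time = 0,
                  signal = c(1.5, 3, 6))
  s <- align_replicates(m)
  expect_equal(s$estimates$estimate, c(1.5, 3, 6))
  expect_equal(s$gel_factors$factor, 1)
  expect_true(all(s$estimates$unreliable))  # single replicates: no CI
})

test_that("a noiseless two-gel design recovers the true factor exactly", {
  x <- c(1, 2, 3, 4)
  m <- data.frame(target = "X", gel = rep(c("ref", "g2"), each = 4),
                  condition = rep(letters[1:4], 2), time = 0,
                  signal = c(x, 2 * x))
  s <- align_replicates(m, reference_rule = function(g) "ref")
  expect_equal(s$gel_factors$factor[s$gel_factors$gel == "g2"], 2,
               tolerance = 1e-12)
  expect_equal(sort(s$estimates$estimate), x, tolerance = 1e-12)
})

test_that("scaling is equivariant under rescaling one gel", {
  set.seed(7)
  x <- exp(rnorm(5)); noise <- exp(rnorm(10, 0, 0.1))
  m <- data.frame(target = "X", gel = rep(c("ref", "g2"), each = 5),
                  condition = rep(letters[1:5], 2), time = 0,
                  signal = c(x, 1.7 * x) * noise)
  s1 <- align_replicates(m, reference_rule = function(g) "ref")
  m2 <- m
  m2$signal[m2$gel == "g2"] <- m2$signal[m2$gel == "g2"] * 3
  s2 <- align_replicates(m2, reference_rule = function(g) "ref")
  f1 <- s1$gel_factors$factor[s1$gel_factors$gel == "g2"]
  f2 <- s2$gel_factors$factor[s2$gel_factors$gel == "g2"]
  expect_equal(f2, 3 * f1, tolerance = 1e-10)
  expect_equal(s1$estimates$estimate, s2$estimates$estimate,
               tolerance = 1e-10)
})

test_that("confidence intervals shrink like 1/sqrt(replicates)", {
  set.seed(99)
  widths <- sapply(c(2, 4, 8), function(N) {
    reps <- replicate(25, {
      cells <- exp(rnorm(6))
      m <- do.call(rbind, lapply(c("ref", "g2"), function(g)
        data.frame(target = "X", gel = g,
                   condition = rep(letters[1:6], each = N), time = 0,
                   signal = rep(cells, each = N) *
                     ifelse(g == "g2", 1.5, 1) *
                     exp(rnorm(6 * N, 0, 0.25)))))
      s <- align_replicates(m, reference_rule = function(g) "ref")
      mean(s$estimates$sigma_log)
    })
    mean(reps)
  })
  slope <- coef(lm(log(widths) ~ log(c(2, 4, 8))))[2]
  expect_equal(unname(slope), -0.5, tolerance = 0.1)
})

test_that("disconnected scaling graphs are reported, not silently dropped", {
  m <- data.frame(target = "X", gel = rep(c("g1", "g2"), each = 2),
                  condition = c("a", "b", "c", "d"), time = 0,
                  signal = 1:4)
  expect_error(align_replicates(m), "disconnected")
  expect_error(align_replicates(transform(m, signal = -1)), "positive")
})

test_that("molecules-per-cell interpolation is exact on a noiseless line", {
  amounts <- c(2e10, 5e10, 1e11, 2e11)
  signals <- amounts * 1e-9
  out <- estimate_molecules_per_cell(amounts, signals,
                                     endogenous_signal = 1e11 * 1e-9,
                                     cells_per_lysate = 1e6)
  expect_equal(out$molecules_per_cell, 1e5, tolerance = 1e-9)
  # doubling the cells per lysate halves the per-cell estimate
  out2 <- estimate_molecules_per_cell(amounts, signals,
                                      endogenous_signal = 1e11 * 1e-9,
                                      cells_per_lysate = 2e6)
  expect_equal(out2$molecules_per_cell, 5e4, tolerance = 1e-9)
  expect_error(
    estimate_molecules_per_cell(amounts, signals, 1e13 * 1e-9, 1e6),
    "extrapolation refused")
})

test_that("generator abundance is recovered within 2x under noise", {
  cc <- generate_calibration(5e4, noise_sd_log = 0.2, seed = 5)
  out <- estimate_molecules_per_cell(cc$amounts, cc$signals,
                                     cc$endogenous_signal,
                                     cc$cells_per_lysate)
  expect_gt(out$molecules_per_cell, 5e4 / 2)
  expect_lt(out$molecules_per_cell, 5e4 * 2)
  expect_true(is.finite(out$sem) && out$sem > 0)
})

test_that("qPCR normalization: one cycle below baseline doubles the fold change", {
  r <- data.frame(gene = rep(c("T", "GAPDH", "HPRT", "TBP"), 2),
                  condition = rep(c("base", "stim"), each = 4), time = 0,
                  Cq = c(30, 18, 26, 27, 29, 18, 26, 27), efficiency = 2)
  out <- normalize_qpcr(r, baseline_condition = "base")
  expect_equal(out$fold_change[out$condition == "stim"], 2, tolerance = 1e-12)
  # a global +1 cycle shift (pipetting) leaves fold changes unchanged
  r2 <- r; r2$Cq[r2$condition == "stim"] <- r2$Cq[r2$condition == "stim"] + 1
  out2 <- normalize_qpcr(r2, baseline_condition = "base")
  expect_equal(out2$fold_change, out$fold_change, tolerance = 1e-12)
})

test_that("samples missing a reference gene are rejected", {
  r <- data.frame(gene = c("T", "GAPDH", "HPRT"), condition = "base",
                  time = 0, Cq = c(30, 18, 26), efficiency = 2)
  expect_error(normalize_qpcr(r, baseline_condition = "base"), "TBP")
  r$Cq[1] <- 60
  expect_error(normalize_qpcr(r, baseline_condition = "base"), "Cq")
})

test_that("single-replicate uncertainties are borrowed from a constant course", {
  set.seed(13)
  # one gel: every cell is a single replicate; the high-dose arm is constant
  m <- data.frame(target = "X", gel = "g1",
                  condition = c(rep("high", 5), "a", "b"),
                  time = c(1:5, 1, 1),
                  signal = c(10 * exp(rnorm(5, 0, 0.2)), 3, 7))
  s <- align_replicates(m)
  expect_true(all(s$estimates$unreliable))
  s2 <- borrow_sigma(s, reference_condition = "high")
  expect_false(any(s2$estimates$unreliable))
  ref <- s2$estimates[s2$estimates$condition == "high", ]
  expect_equal(unique(round(s2$estimates$sigma_log, 12)),
               round(sd(log(ref$estimate)), 12))
})
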