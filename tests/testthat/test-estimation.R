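test_that("the weak L2 prior contributes one at five decades from 1", {
  expect_equal(l2_prior(log10(1e5)), 1)
  expect_equal(l2_prior(log10(1)), 0)
  expect_equal(l2_prior(log10(1e-5)), 1)
  expect_equal(l2_prior(c(5, -5)), 2)
})

p_nom <- nominal_parameters()
conds1 <- list(tc = condition(prestim_dose = 1400))
times1 <- c(0.5, 1, 2, 4, 8, 24)

make_noiseless_data <- function(obs = c("pSTAT1_Cyt", "USP18")) {
  tr <- simulate_model(p_nom, conds1$tc, t_grid = c(0, times1))
  ob <- compute_observables(tr, p_nom, obs)
  do.call(rbind, lapply(obs, function(o)
    data.frame(observable = o, condition = "tc", time = times1,
               estimate = ob[-1, o], sigma = 0.1 * abs(ob[-1, o]) + 1)))
}

test_that("the objective is zero on self-consistent data and quadratic in offsets", {
  data <- make_noiseless_data()
  free <- c("actSTAT1", "synthUSP18mRNA")
  obj <- make_objective(data, p_nom, free, conds1, prior = "none")
  th0 <- unclass(p_nom)[free]
  expect_lt(obj(th0), 1e-6)
  # adding k sigma to one data point raises the objective by k^2
  for (k in c(1, 3)) {
    d2 <- data; d2$estimate[4] <- d2$estimate[4] + k * d2$sigma[4]
    obj2 <- make_objective(d2, p_nom, free, conds1, prior = "none")
    expect_equal(obj2(th0), k^2, tolerance = 1e-4)
  }
  # with the prior the objective adds the L2 term
  objp <- make_objective(data, p_nom, free, conds1, prior = "l2")
  expect_equal(objp(th0) - obj(th0), l2_prior(th0), tolerance = 1e-6)
  expect_true(is.infinite(obj(c(NA, 0))))
})

test_that("sensitivity-based gradient matches finite differences", {
  data <- make_noiseless_data()
  free <- c("actSTAT1", "synthUSP18mRNA", "KiUSP18")
  obj <- make_objective(data, p_nom, free, conds1, prior = "none",
                        rtol = 1e-10, atol = 1e-10)
  th <- unclass(p_nom)[free] + c(0.1, -0.1, 0.05)
  g_sens <- objective_gradient(obj, th)
  h <- 1e-5
  g_fd <- vapply(seq_along(th), function(j) {
    e <- numeric(length(th)); e[j] <- h
    (obj(th + e) - obj(th - e)) / (2 * h)
  }, 0)
  expect_lt(max(abs(g_sens - g_fd) / pmax(abs(g_fd), 1e-8)), 1e-4)
})

test_that("multi-start optimization solves a convex toy from every start", {
  obj <- function(th) sum((th - c(1, -2))^2) + 3
  ms <- multistart(obj, n_starts = 12, start_box = rbind(c(-5, -5), c(5, 5)),
                   seed = 2)
  expect_true(all(abs(ms$results$objective - 3) < 1e-8))
  # waterfall is sorted non-decreasing, one plateau
  expect_true(!is.unsorted(waterfall(ms)))
  expect_true(all(ms$plateaus == 1))
  expect_equal(unname(ms$best$par), c(1, -2), tolerance = 1e-5)
  expect_error(multistart(function(th) Inf, n_starts = 2,
                          start_box = rbind(-1, 1)), "failed")
})

test_that("multi-start recovers generator parameters from model data", {
  data <- make_noiseless_data()
  free <- c("actSTAT1", "synthUSP18mRNA", "KiUSP18")
  obj <- make_objective(data, p_nom, free, conds1, prior = "none")
  th0 <- unclass(p_nom)[free]
  box <- rbind(th0 - 0.5, th0 + 0.5); colnames(box) <- free
  ms <- multistart(obj, n_starts = 6, start_box = box, seed = 3)
  expect_lt(max(abs(ms$best$par - th0)), 0.02)
})

test_that("profiles of a linear-Gaussian model are the analytic parabolas", {
  toy <- toy_linear_gaussian()
  opt <- nlminb(c(0, 0), toy$obj)
  expect_equal(unname(opt$par), unname(toy$coef), tolerance = 1e-6)
  for (j in 1:2) {
    pr <- profile_likelihood(toy$obj, list(par = opt$par,
                                           objective = opt$objective),
                             param = j, level = 0.95)
    expect_equal(pr$class, "identifiable")
    # Wald interval: theta_hat +/- 1.96 se, exact for linear models
    want <- toy$coef[j] + c(-1, 1) * sqrt(qchisq(0.95, 1)) * toy$se[j]
    expect_equal(unname(pr$ci), want, tolerance = 0.01, ignore_attr = TRUE)
    # profile values follow the parabola (obj rises quadratically)
    ok <- pr$curve[!is.na(pr$curve$objective), ]
    resid <- ok$objective - (opt$objective +
      (ok$value - opt$par[j])^2 / toy$se[j]^2)
    expect_lt(max(abs(resid)), 0.05 * qchisq(0.95, 1))
  }
})

test_that("a structurally absent parameter profiles flat on both sides", {
  obj <- function(th) (th[1] - 1)^2  # th[2] never enters
  pr <- profile_likelihood(obj, list(par = c(1, 0), objective = 0),
                           param = 2, box_half_width = 3)
  expect_equal(pr$class, "open_both")
  expect_true(all(is.na(pr$ci)))
})

test_that("rates observed only through their sum are one-sided on log scale", {
  # data inform k1 + k2 = 2; parameters are log10(k1), log10(k2)
  obj <- function(th) ((10^th[1] + 10^th[2]) - 2)^2 / 0.01
  opt <- nlminb(c(-0.1, -0.1), obj)
  pr1 <- profile_likelihood(obj, list(par = opt$par,
                                      objective = opt$objective),
                            param = 1, box_half_width = 5)
  # each rate can vanish (lower side open) but not exceed the sum
  expect_equal(pr1$class, "open_left")
  expect_true(is.finite(pr1$ci["upper"]))
  # the sum itself is identifiable
  objs <- function(phi) ((10^phi[1]) - 2)^2 / 0.01
  prs <- profile_likelihood(objs, list(par = log10(2), objective = 0),
                            param = 1)
  expect_equal(prs$class, "identifiable")
})

test_that("identifiability classes survive monotone reparameterization", {
  toy <- toy_linear_gaussian()
  opt <- nlminb(c(0, 0), toy$obj)
  # reparameterize the slope as its cube root (strictly monotone)
  obj2 <- function(th) toy$obj(c(th[1], th[2]^3))
  opt2 <- nlminb(c(opt$par[1], sign(opt$par[2]) * abs(opt$par[2])^(1 / 3)),
                 obj2)
  pr <- profile_likelihood(obj2, list(par = opt2$par,
                                      objective = opt2$objective), param = 2)
  expect_equal(pr$class, "identifiable")
})

test_that("prediction profiles reproduce the analytic interval of a linear model", {
  toy <- toy_linear_gaussian()
  opt <- nlminb(c(0, 0), toy$obj)
  # predict the mean response at x0
  x0 <- 0.5
  pred <- function(th) th[1] + th[2] * x0
  pp <- prediction_profile(toy$obj, list(par = opt$par,
                                         objective = opt$objective),
                           pred, level = 0.68)
  X <- cbind(1, toy$x)
  V <- solve(t(X) %*% X) * toy$sigma^2
  se <- sqrt(t(c(1, x0)) %*% V %*% c(1, x0))[1]
  want <- pred(opt$par) + c(-1, 1) * sqrt(qchisq(0.68, 1)) * se
  expect_equal(unname(pp$interval), want, tolerance = 0.01,
               ignore_attr = TRUE)
  # the interval always contains the best-fit prediction
  expect_true(pp$interval[1] <= pp$prediction &&
                pp$prediction <= pp$interval[2])
})

test_that("prediction interval collapses in the zero-noise limit", {
  # objective sharply determined (tiny sigma): interval ~ point prediction
  obj <- function(th) sum((th - c(1, 2))^2) / 1e-6
  pp <- prediction_profile(obj, list(par = c(1, 2), objective = 0),
                           function(th) th[1] + th[2], step = 0.01)
  expect_lt(diff(pp$interval), 0.01)
})

test_that("BIC comparison follows k ln(n) - 2 ln(L)", {
  fits <- list(small = list(objective = 100, k = 10),
               large = list(objective = 100, k = 12))
  cmp <- compare_models(fits, n_data = 100)
  expect_equal(attr(cmp, "winner"), "small")
  expect_equal(cmp$bic[cmp$model == "large"] -
                 cmp$bic[cmp$model == "small"], 2 * log(100))
  # a parameter that cannot reduce the objective never lowers the BIC
  expect_gte(cmp$bic[cmp$model == "large"], cmp$bic[cmp$model == "small"])
  expect_error(compare_models(list(a = list(objective = 1, k = 1,
                                            n_data = 10),
                                   b = list(objective = 1, k = 1,
                                            n_data = 20)), 10),
               "different size")
})
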