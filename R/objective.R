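# Maximum-likelihood objective for calibrating the model against scaled data.
#
# The objective is the weighted residual sum of squares (-2 log L up to a
# constant) plus, optionally, the weak L2 prior on the log10 parameters. The
# steady-state transform is applied inside every evaluation, so basal
# synthesis rates track the current parameter values exactly.

#' Weak L2 prior on log10 parameters
#'
#' Contributes 1 to the objective when a parameter differs by five orders of
#' magnitude from 1: `sum((log10(theta)/5)^2)`.
#'
#' @param log10_params numeric vector of log10 parameter values.
#' @return penalty value.
#' @export
l2_prior <- function(log10_params) sum((log10_params / 5)^2)

#' Build a maximum-likelihood objective for the signaling model
#'
#' @param data data.frame with columns `observable`, `condition`, `time`,
#'   `estimate`, `sigma` (1-sigma uncertainties, > 0).
#' @param pars full `ifndyn_parset` supplying the fixed parameter values.
#' @param free character vector of parameter names estimated (the objective's
#'   argument is their log10 vector, in this order).
#' @param conditions named list of [condition()] objects; names must cover
#'   `data$condition`.
#' @param variant receptor variant to simulate.
#' @param prior `"l2"` (default) adds the weak L2 prior over the free
#'   parameters; `"none"` gives the pure data objective (used for
#'   identifiability analysis, where the priors are subtracted).
#' @param rtol,atol solver tolerances used inside the objective.
#' @return function `f(theta)` returning the objective value (`+Inf` on
#'   simulation failure, with the cause in attribute `cause`); carries
#'   attributes `free`, `n_data`, and `simulate_fit` (a function returning
#'   fitted observable values for diagnostics).
#' @export
make_objective <- function(data, pars, free, conditions,
                           variant = "SOCS1_or_SOCS1xUSP18",
                           prior = c("l2", "none"),
                           rtol = 1e-6, atol = 1e-6) {
  prior <- match.arg(prior)
  req <- c("observable", "condition", "time", "estimate", "sigma")
  stopifnot(all(req %in% names(data)), all(data$sigma > 0),
            all(free %in% names(pars)),
            all(data$condition %in% names(conditions)))
  split_data <- split(data, data$condition)

  sim_fit <- function(theta) {
    p <- pars
    p[free] <- theta
    out <- numeric(nrow(data)); idx <- 1L
    for (cn in names(split_data)) {
      d <- split_data[[cn]]
      tg <- sort(unique(c(0, d$time, conditions[[cn]]$stim_time)))
      tr <- simulate_model(p, conditions[[cn]], t_grid = tg,
                           variant = variant, rtol = rtol, atol = atol)
      ob <- compute_observables(tr, p, unique(d$observable))
      rows <- match(d$time, ob[, "time"])
      vals <- ob[cbind(rows, match(d$observable, colnames(ob)))]
      out[match(rownames(d), rownames(data))] <- vals
    }
    out
  }

  f <- function(theta) {
    if (any(!is.finite(theta))) return(Inf)
    vals <- try(sim_fit(theta), silent = TRUE)
    if (inherits(vals, "try-error"))
      return(structure(Inf, cause = attr(vals, "condition")$message))
    if (any(!is.finite(vals)))
      return(structure(Inf, cause = "non-finite simulated observables"))
    obj <- sum(((data$estimate - vals) / data$sigma)^2)
    if (prior == "l2") obj <- obj + l2_prior(theta)
    obj
  }
  attr(f, "free") <- free
  attr(f, "n_data") <- nrow(data)
  attr(f, "prior") <- prior
  attr(f, "simulate_fit") <- sim_fit
  attr(f, "data") <- data
  attr(f, "pars") <- pars
  attr(f, "conditions") <- conditions
  attr(f, "variant") <- variant
  f
}

# Direct compiled-RHS evaluation with an explicit parameter vector.
.rhs_eval <- function(t, y, p) {
  .C("ifndyn_rhs_eval", as.double(t), as.double(y), as.double(p),
     ydot = double(length(y)), PACKAGE = "ifndyn")$ydot
}

#' Sensitivity-based gradient of the model objective
#'
#' Computes the gradient of an objective built by [make_objective()] by
#' integrating the forward variational equations dS/dt = J S + df/dp for each
#' condition, with the state Jacobian J and the parameter derivatives df/dp
#' formed by directional finite differences of the compiled right-hand side,
#' and the chain rule through the steady-state transform handled by finite
#' differences of the (algebraic) transform itself.
#'
#' @param objective function from [make_objective()].
#' @param theta log10 values of the free parameters.
#' @param rtol,atol tolerances of the sensitivity integration.
#' @return gradient vector (same length/order as `theta`).
#' @export
objective_gradient <- function(objective, theta, rtol = 1e-8, atol = 1e-6) {
  free <- attr(objective, "free")
  data <- attr(objective, "data")
  pars <- attr(objective, "pars")
  conditions <- attr(objective, "conditions")
  variant <- attr(objective, "variant")
  k <- length(theta); n <- 41L
  grad <- numeric(k)

  for (cn in unique(data$condition)) {
    d <- data[data$condition == cn, ]
    cond <- conditions[[cn]]
    build <- function(th) {
      p <- pars; p[free] <- th
      p2 <- .condition_pars(p, cond)
      ss <- apply_steady_state(p2)
      cp <- .c_parms(ss, variant, cond$knockdown_factor, cond$overexpression)
      list(cp = cp, y0 = ss$y0, pars = p)
    }
    b0 <- build(theta)
    h <- 1e-5
    dcp <- matrix(0, length(b0$cp), k); dy0 <- matrix(0, n, k)
    for (j in seq_len(k)) {
      thp <- theta; thp[j] <- thp[j] + h
      thm <- theta; thm[j] <- thm[j] - h
      bp <- build(thp); bm <- build(thm)
      dcp[, j] <- (bp$cp - bm$cp) / (2 * h)
      dy0[, j] <- (bp$y0 - bm$y0) / (2 * h)
    }
    sched <- .dose_schedule(cond)
    tmax <- max(d$time, sched$times)
    bounds <- c(sched$times, tmax)
    times_out <- sort(unique(c(d$time, sched$times, tmax)))

    aug_rhs <- function(t, state, parms) {
      y <- state[1:n]
      S <- matrix(state[-(1:n)], n, k)
      f0 <- .rhs_eval(t, y, parms$cp)
      eps <- 1e-7 * max(1, sqrt(sum(y^2)))
      JS <- matrix(0, n, k); FP <- matrix(0, n, k)
      for (j in seq_len(k)) {
        sj <- S[, j]; nrm <- sqrt(sum(sj^2))
        if (nrm > 0) {
          e <- eps / nrm
          JS[, j] <- (.rhs_eval(t, y + e * sj, parms$cp) - f0) / e
        }
        dp <- dcp[, j]
        npn <- sqrt(sum(dp^2))
        if (npn > 0) {
          ep <- 1e-7 * max(1, sqrt(sum(parms$cp^2))) / npn
          FP[, j] <- (.rhs_eval(t, y, parms$cp + ep * dp) - f0) / ep
        }
      }
      list(c(f0, as.vector(JS + FP)))
    }

    state <- c(b0$y0, as.vector(dy0))
    sol_rows <- NULL
    for (seg in seq_along(sched$times)) {
      cp <- b0$cp; cp["IFN"] <- sched$levels[seg]
      # IFN level is event-set, not parameter-dependent: zero its derivative
      dcp["IFN" == names(b0$cp), ] <- 0
      t0 <- bounds[seg]; t1 <- bounds[seg + 1]
      if (t1 <= t0) next
      seg_t <- sort(unique(c(t0, times_out[times_out > t0 & times_out <= t1])))
      sol <- deSolve::lsoda(state, seg_t, aug_rhs, parms = list(cp = cp),
                            rtol = rtol, atol = atol, maxsteps = 20000)
      state <- sol[nrow(sol), -1]
      keep <- sol[, 1] %in% times_out & (sol[, 1] > t0 | seg == 1)
      sol_rows <- rbind(sol_rows, sol[keep, , drop = FALSE])
    }
    # observable sensitivities and residual accumulation
    p0 <- pars; p0[free] <- theta
    nat <- natural_scale(p0)
    for (i in seq_len(nrow(d))) {
      row <- sol_rows[match(d$time[i], sol_rows[, 1]), -1]
      y <- row[1:n]; S <- matrix(row[-(1:n)], n, k)
      w <- .obs_map[[d$observable[i]]]
      widx <- match(names(w), .state_names)
      ob <- d$observable[i]
      sc <- if (ob %in% .scaled_obs) nat[[paste0("scale_", ob)]] else 1
      val <- sc * sum(w * y[widx])
      dval <- sc * as.vector(t(w) %*% S[widx, , drop = FALSE])
      if (ob %in% .scaled_obs) {
        snm <- paste0("scale_", ob)
        j <- match(snm, free)
        if (!is.na(j)) dval[j] <- dval[j] + log(10) * sc * sum(w * y[widx])
      }
      if (ob %in% .offset_obs) {
        onm <- paste0("offset_", ob)
        val <- val + nat[[onm]]
        j <- match(onm, free)
        if (!is.na(j)) dval[j] <- dval[j] + log(10) * nat[[onm]]
      }
      r <- (d$estimate[i] - val) / d$sigma[i]
      grad <- grad - 2 * r * dval / d$sigma[i]
    }
  }
  if (attr(objective, "prior") == "l2") grad <- grad + 2 * theta / 25
  grad
}
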