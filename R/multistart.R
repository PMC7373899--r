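# Deterministic multi-start maximum-likelihood optimization with waterfall
# summary, mirroring the calibration strategy of multi-start trust-region
# fitting: many random initial parameter vectors, each optimized by a
# quasi-Newton method, results sorted by objective value.

#' Multi-start optimization
#'
#' @param objective function of a numeric parameter vector returning a scalar
#'   (e.g. from [make_objective()], or any test objective).
#' @param n_starts number of random starts (>= 1).
#' @param start_box 2 x k matrix (rows: lower, upper) of the uniform start
#'   distribution per parameter; defaults to log10 range [-5, 5] in every
#'   coordinate (matching the prior scale). Column names give parameter
#'   names.
#' @param seed RNG seed for the start draws (recorded in the result).
#' @param n_pars number of parameters (needed if `start_box` is missing and
#'   the objective carries no `free` attribute).
#' @param include optional matrix of additional start points (rows), e.g. the
#'   truth-agnostic default start of a transfer fit.
#' @param control passed to [stats::nlminb()].
#' @param plateau_tol objective tolerance for grouping results into plateaus
#'   (default 0.1 on the -2 log L scale).
#' @return object of class `ifndyn_multistart`: list with `results`
#'   (data.frame: start, objective, convergence, sorted non-decreasing),
#'   `pars` (matrix of optimized parameters, same order), `best` (list par,
#'   objective), `plateaus` (group index per result), `seed`.
#' @export
multistart <- function(objective, n_starts = 50, start_box = NULL,
                       seed = 1L, n_pars = NULL, include = NULL,
                       control = list(iter.max = 300, eval.max = 600),
                       plateau_tol = 0.1) {
  stopifnot(n_starts >= 1)
  if (is.null(start_box)) {
    k <- n_pars %||% length(attr(objective, "free"))
    if (is.null(k) || k == 0) stop("cannot infer parameter dimension")
    start_box <- rbind(rep(-5, k), rep(5, k))
    colnames(start_box) <- attr(objective, "free")
  }
  k <- ncol(start_box)
  set.seed(seed)
  starts <- t(replicate(n_starts,
                        runif(k, start_box[1, ], start_box[2, ])))
  if (!is.null(include)) starts <- rbind(include, starts)

  res <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    fit <- try(nlminb(starts[i, ], objective, control = control),
               silent = TRUE)
    if (inherits(fit, "try-error") || !is.finite(fit$objective)) {
      res[[i]] <- list(par = starts[i, ], objective = Inf, conv = NA_integer_)
    } else {
      res[[i]] <- list(par = fit$par, objective = fit$objective,
                       conv = fit$convergence)
    }
  }
  objs <- vapply(res, `[[`, 0, "objective")
  if (all(!is.finite(objs))) stop("all optimization starts failed")
  ord <- order(objs)
  objs <- objs[ord]
  pars <- do.call(rbind, lapply(res[ord], `[[`, "par"))
  colnames(pars) <- colnames(start_box)
  # plateau grouping: consecutive gaps larger than the tolerance start a new
  # group (the waterfall's steps)
  plateaus <- cumsum(c(1, diff(objs) > plateau_tol))
  structure(list(
    results = data.frame(start = ord, objective = objs,
                         convergence = vapply(res[ord], `[[`, 0L, "conv")),
    pars = pars,
    best = list(par = pars[1, ], objective = objs[1]),
    plateaus = plateaus, seed = seed),
    class = "ifndyn_multistart")
}

#' @export
print.ifndyn_multistart <- function(x, ...) {
  n <- nrow(x$results)
  cat(sprintf("multi-start fit: %d starts, best objective %.6g,\n", n,
              x$best$objective))
  cat(sprintf("  global plateau reached by %d of %d starts (tol grouping)\n",
              sum(x$plateaus == 1), n))
  invisible(x)
}

#' Waterfall values of a multi-start fit
#' @param fit an `ifndyn_multistart`.
#' @param n_best number of best fits to return (default all).
#' @return numeric vector of sorted objective values.
#' @export
waterfall <- function(fit, n_best = Inf) {
  head(fit$results$objective, n_best)
}
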