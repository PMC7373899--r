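# Elastic-net estimation of cell-type-specific parameter ratios.
#
# A new cell type is parameterized by log10 ratios Delta_j relative to the
# calibrated control model; an elastic-net penalty lambda * (|Delta| +
# Delta^2) shrinks ratios toward the control values (L1 and L2 part equal at
# one decade by construction). Model size is selected by a modified BIC that
# counts only the ratios pulled off zero.

#' Elastic-net penalty on ratio parameters
#'
#' `sum(lambda * (|Delta_j| + Delta_j^2))`: at |Delta_j| = 1 decade the L1
#' and L2 contributions are equal.
#'
#' @param delta_vector log10 ratio parameters.
#' @param lam regularization strength (> 0).
#' @param eps smoothing of |x| as sqrt(x^2 + eps^2) (for the optimizer);
#'   `eps = 0` gives the exact penalty.
#' @return penalty value.
#' @export
elastic_net_penalty <- function(delta_vector, lam, eps = 0) {
  stopifnot(lam > 0)
  l1 <- if (eps > 0) sqrt(delta_vector^2 + eps^2) - eps else abs(delta_vector)
  sum(lam * (l1 + delta_vector^2))
}

#' Fit a regularization path of cell-type ratio parameters
#'
#' For each regularization strength, the data objective plus elastic-net
#' penalty is minimized over the ratio parameters by multi-start optimization
#' (smoothed |x|); the set of ratios exceeding `zero_tol` in absolute value
#' is recorded.
#'
#' @param objective data objective as a function of the ratio vector (built
#'   by the caller around [make_objective()] with the control parameters
#'   fixed, or any test objective). Must carry/accept `n_ratio` parameters.
#' @param n_ratio number of ratio parameters.
#' @param lam_grid numeric vector of regularization strengths (> 0).
#' @param n_starts multi-starts per lambda (the zero vector is always
#'   included as a start).
#' @param seed RNG seed.
#' @param zero_tol threshold in decades below which a ratio counts as zero
#'   (default 1e-3).
#' @param start_sd standard deviation of the random starts around zero.
#' @param control passed to [stats::nlminb()].
#' @return object of class `ifndyn_enet_path`: list of per-lambda records
#'   (lambda, par, objective [data part], penalized, nonzero index vector),
#'   plus `zero_tol`, `seed`.
#' @export
fit_path <- function(objective, n_ratio, lam_grid, n_starts = 10, seed = 1L,
                     zero_tol = 1e-3, start_sd = 0.3,
                     control = list(iter.max = 300)) {
  if (length(lam_grid) == 0) stop("empty lambda grid")
  stopifnot(all(lam_grid > 0), n_ratio >= 1)
  eps <- 1e-6
  # solve from the strongest penalty downward, warm-starting each lambda with
  # the previous solution (the path is continuous in lambda)
  ord <- order(lam_grid, decreasing = TRUE)
  path <- vector("list", length(lam_grid))
  warm <- NULL
  for (li in ord) {
    lam <- lam_grid[li]
    pen_obj <- function(delta)
      objective(delta) + elastic_net_penalty(delta, lam, eps = eps)
    set.seed(seed + li)
    starts <- rbind(rep(0, n_ratio), warm,
                    matrix(rnorm(n_starts * n_ratio, 0, start_sd),
                           ncol = n_ratio))
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      fit <- try(nlminb(starts[i, ], pen_obj, control = control),
                 silent = TRUE)
      if (inherits(fit, "try-error") || !is.finite(fit$objective)) next
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
    if (is.null(best)) stop("all starts failed at lambda = ", lam)
    # proximal polish: the smoothed-|x| optimizer leaves noise-absorbing
    # components at small nonzero values; zero each component (smallest
    # first) whenever that does not increase the penalized objective, then
    # re-optimize the survivors
    par <- best$par
    cur <- pen_obj(par)
    for (j in order(abs(par))) {
      if (par[j] == 0) next
      cand <- par; cand[j] <- 0
      v <- pen_obj(cand)
      if (is.finite(v) && v <= cur + 1e-9) { par <- cand; cur <- v }
    }
    nz <- which(abs(par) > zero_tol)
    if (length(nz) > 0 && length(nz) < n_ratio) {
      wrap <- function(th) {
        d <- numeric(n_ratio); d[nz] <- th
        pen_obj(d)
      }
      ref <- try(nlminb(par[nz], wrap, control = control), silent = TRUE)
      if (!inherits(ref, "try-error") && is.finite(ref$objective) &&
          ref$objective <= cur) {
        par <- numeric(n_ratio); par[nz] <- ref$par
      }
    }
    warm <- par
    par[abs(par) <= zero_tol] <- 0
    path[[li]] <- list(lambda = lam, par = par,
                       objective = objective(par),
                       penalized = best$objective,
                       nonzero = which(par != 0))
  }
  structure(list(path = path, zero_tol = zero_tol, seed = seed,
                 n_ratio = n_ratio),
            class = "ifndyn_enet_path")
}

#' Select the cell-type model along a regularization path
#'
#' Minimizes the modified information criterion
#' `4 * ln(n) * k - 2 * ln(L)`, where `k` is the number of ratio parameters
#' different from the control model and the data objective plays `-2 ln(L)`.
#' Ties are broken toward smaller `k`, then smaller lambda. The winner is
#' re-fit without penalty on its nonzero set before reporting (avoiding
#' shrinkage bias).
#'
#' @param path an `ifndyn_enet_path`.
#' @param objective the unpenalized data objective (for the refit).
#' @param n_data number of data points.
#' @param refit set `FALSE` to skip the post-selection refit.
#' @param control passed to the refit optimizer.
#' @return list with `nonzero` (indices), `k`, `lambda`, `par` (refit ratio
#'   vector), `objective` (refit data objective), `criterion`, and the full
#'   `table` of per-lambda criteria.
#' @export
select_celltype_model <- function(path, objective, n_data, refit = TRUE,
                                  control = list(iter.max = 300)) {
  stopifnot(inherits(path, "ifndyn_enet_path"), n_data >= 1)
  tab <- do.call(rbind, lapply(path$path, function(r) {
    data.frame(lambda = r$lambda, k = length(r$nonzero),
               objective = r$objective,
               criterion = 4 * log(n_data) * length(r$nonzero) + r$objective)
  }))
  if (!refit) {
    ord <- order(tab$criterion, tab$k, tab$lambda)
    win <- path$path[[ord[1]]]
    return(list(nonzero = win$nonzero, k = length(win$nonzero),
                lambda = win$lambda, par = win$par,
                objective = win$objective,
                criterion = tab$criterion[ord[1]], table = tab))
  }
  # candidate supports: every distinct support along the path, plus the
  # magnitude-nested supports of every path solution (relaxed selection:
  # shrinkage orders the ratios; the criterion is evaluated at the
  # penalty-free maximum-likelihood refit of each candidate support)
  supports <- list(integer(0))
  lam_of <- list(NA_real_)
  add <- function(nz, lam) {
    key <- paste(nz, collapse = ",")
    keys <- vapply(supports, paste, "", collapse = ",")
    if (!key %in% keys) {
      supports[[length(supports) + 1]] <<- nz
      lam_of[[length(lam_of) + 1]] <<- lam
    }
  }
  for (r in path$path) {
    add(r$nonzero, r$lambda)
    mags <- abs(r$par)
    ord_m <- order(mags, decreasing = TRUE)
    for (k in seq_len(sum(mags > 0)))
      add(sort(ord_m[seq_len(k)]), r$lambda)
  }
  evals <- lapply(seq_along(supports), function(si) {
    nz <- supports[[si]]
    if (length(nz) == 0) {
      obj <- objective(numeric(path$n_ratio))
      return(list(nonzero = nz, par = numeric(path$n_ratio), objective = obj,
                  criterion = obj, lambda = lam_of[[si]]))
    }
    wrap <- function(th) {
      delta <- numeric(path$n_ratio); delta[nz] <- th
      objective(delta)
    }
    # warm start from the best path estimate of this support
    st <- rep(0, length(nz))
    for (r in path$path)
      if (all(nz %in% r$nonzero)) { st <- r$par[nz]; break }
    fit <- try(nlminb(st, wrap, control = control), silent = TRUE)
    if (inherits(fit, "try-error") || !is.finite(fit$objective))
      return(NULL)
    par <- numeric(path$n_ratio); par[nz] <- fit$par
    list(nonzero = nz, par = par, objective = fit$objective,
         criterion = 4 * log(n_data) * length(nz) + fit$objective,
         lambda = lam_of[[si]])
  })
  evals <- Filter(Negate(is.null), evals)
  crit <- vapply(evals, `[[`, 0, "criterion")
  ks <- vapply(evals, function(e) length(e$nonzero), 0L)
  win <- evals[[order(crit, ks)[1]]]
  list(nonzero = win$nonzero, k = length(win$nonzero), lambda = win$lambda,
       par = win$par, objective = win$objective, criterion = win$criterion,
       table = tab,
       candidates = data.frame(
         k = ks, criterion = crit,
         support = vapply(evals, function(e)
           paste(e$nonzero, collapse = ","), "")))
}
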