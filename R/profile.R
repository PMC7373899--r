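# Profile likelihood for identifiability analysis and prediction profiles.
#
# The profile of a parameter is the objective re-optimized over all other
# parameters while the profiled one is stepped outward from the optimum;
# confidence intervals are read off where the profile crosses the optimum
# plus a chi-square threshold, and a parameter is classified by which sides
# reach the threshold before the search box ends.

#' Profile likelihood of one parameter
#'
#' @param objective objective function over the full parameter vector.
#' @param best_fit list with `par` (optimum) and `objective` (its value).
#' @param param index or name (of `names(best_fit$par)`) of the profiled
#'   parameter.
#' @param level confidence level; the threshold is
#'   `qchisq(level, 1)` above the optimum (default 0.95, i.e. 3.84).
#' @param step initial step size on the parameter scale (log10 for model
#'   parameters; default 0.1).
#' @param box_half_width maximal distance from the optimum explored on each
#'   side (default 5 decades).
#' @param max_steps maximal number of profile points per side.
#' @param control passed to the inner [stats::nlminb()] re-optimizations.
#' @return object of class `ifndyn_profile`: data.frame `curve` (value,
#'   objective, side), `ci` (lower, upper; NA when open), `class` (one of
#'   `identifiable`, `open_left`, `open_right`, `open_both`), `threshold`.
#' @export
profile_likelihood <- function(objective, best_fit, param, level = 0.95,
                               step = 0.1, box_half_width = 5,
                               max_steps = 100,
                               control = list(iter.max = 200)) {
  par0 <- best_fit$par
  if (is.character(param)) param <- match(param, names(par0))
  stopifnot(!is.na(param), param >= 1, param <= length(par0))
  thresh <- best_fit$objective + qchisq(level, df = 1)

  reopt <- function(fixed_value, start_rest) {
    if (length(par0) == 1L) {
      val <- objective(fixed_value)
      return(list(objective = val, rest = numeric(0)))
    }
    wrap <- function(th_rest) {
      th <- numeric(length(par0))
      th[-param] <- th_rest; th[param] <- fixed_value
      objective(th)
    }
    fit <- try(nlminb(start_rest, wrap, control = control), silent = TRUE)
    if (inherits(fit, "try-error"))
      return(list(objective = NA_real_, rest = start_rest))
    list(objective = fit$objective, rest = fit$par)
  }

  one_side <- function(direction) {
    out <- NULL
    rest <- par0[-param]
    x <- par0[param]
    h <- step
    last_obj <- best_fit$objective
    for (i in seq_len(max_steps)) {
      x_new <- x + direction * h
      if (abs(x_new - par0[param]) > box_half_width) break
      r <- reopt(x_new, rest)
      if (is.na(r$objective)) { # failed point: mark, shrink step, continue
        out <- rbind(out, data.frame(value = x_new, objective = NA_real_))
        h <- h / 2
        next
      }
      out <- rbind(out, data.frame(value = x_new, objective = r$objective))
      rest <- r$rest
      # adaptive step: target objective increments of ~ a tenth of the
      # threshold height
      dobj <- abs(r$objective - last_obj)
      target <- qchisq(level, 1) / 10
      if (dobj > 2 * target) h <- max(h / 2, 1e-3)
      else if (dobj < target / 4) h <- min(h * 2, 1)
      x <- x_new
      last_obj <- r$objective
      if (r$objective > thresh) break
    }
    out
  }

  left <- one_side(-1); right <- one_side(+1)
  curve <- rbind(
    if (!is.null(left)) cbind(left[rev(seq_len(nrow(left))), ], side = "left"),
    data.frame(value = par0[param], objective = best_fit$objective,
               side = "center"),
    if (!is.null(right)) cbind(right, side = "right"))

  cross <- function(side_df, direction) {
    ok <- side_df[!is.na(side_df$objective), ]
    if (nrow(ok) == 0 || max(ok$objective) < thresh) return(NA_real_)
    above <- which(ok$objective > thresh)[1]
    if (above == 1) {
      x0 <- par0[param]; y0 <- best_fit$objective
    } else {
      x0 <- ok$value[above - 1]; y0 <- ok$objective[above - 1]
    }
    x1 <- ok$value[above]; y1 <- ok$objective[above]
    x0 + (thresh - y0) / (y1 - y0) * (x1 - x0)
  }
  lower <- unname(cross(left, -1)); upper <- unname(cross(right, +1))
  cls <- if (is.na(lower) && is.na(upper)) "open_both"
  else if (is.na(lower)) "open_left"
  else if (is.na(upper)) "open_right"
  else "identifiable"
  structure(list(curve = curve, ci = c(lower = lower, upper = upper),
                 class = cls, threshold = thresh, param = param,
                 level = level),
            class = "ifndyn_profile")
}

#' @export
print.ifndyn_profile <- function(x, ...) {
  cat(sprintf("profile likelihood: parameter %s, class %s, %g%% CI [%.4g, %.4g]\n",
              x$param, x$class, 100 * x$level, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Prediction profile likelihood interval
#'
#' Confidence interval for a scalar prediction: the objective is re-optimized
#' under the constraint that the prediction equals a fixed value, which is
#' stepped outward from the best-fit prediction until the constrained
#' objective exceeds the threshold for the requested level.
#'
#' @param objective objective over the parameter vector.
#' @param best_fit list with `par` and `objective`.
#' @param predictor function mapping a parameter vector to the scalar
#'   prediction.
#' @param level confidence level (default 0.68, the error-bar convention).
#' @param step initial step as a fraction of `max(|prediction|, scale0)`.
#' @param scale0 fallback prediction scale when the best-fit prediction is 0.
#' @param penalty weight of the quadratic constraint enforcement.
#' @param max_steps maximal steps per side.
#' @return list with `interval` (lower, upper), `prediction` (best fit),
#'   `threshold`.
#' @export
prediction_profile <- function(objective, best_fit, predictor, level = 0.68,
                               step = 0.05, scale0 = 1, penalty = 1e6,
                               max_steps = 60) {
  p_hat <- predictor(best_fit$par)
  if (!is.finite(p_hat)) stop("non-finite predictor at the best fit")
  thresh <- best_fit$objective + qchisq(level, df = 1)
  scale <- max(abs(p_hat), scale0)

  constrained <- function(target, start) {
    wrap <- function(th) {
      v <- objective(th)
      if (!is.finite(v)) return(v)
      v + penalty * ((predictor(th) - target) / scale)^2
    }
    fit <- try(nlminb(start, wrap, control = list(iter.max = 200)),
               silent = TRUE)
    if (inherits(fit, "try-error")) return(list(obj = NA_real_, par = start))
    list(obj = objective(fit$par) +
           0 * fit$objective, par = fit$par,
         pen_obj = fit$objective)
  }

  one_side <- function(direction) {
    par <- best_fit$par
    target <- p_hat
    bound <- NA_real_
    last_ok <- p_hat; last_obj <- best_fit$objective
    for (i in seq_len(max_steps)) {
      target <- target + direction * step * scale
      r <- constrained(target, par)
      if (is.na(r$obj)) break
      par <- r$par
      if (r$pen_obj > thresh) {
        # interpolate the crossing on the prediction axis
        bound <- last_ok + (thresh - last_obj) /
          (r$pen_obj - last_obj) * (target - last_ok)
        break
      }
      last_ok <- target; last_obj <- r$pen_obj
    }
    bound
  }
  lo <- one_side(-1); hi <- one_side(+1)
  list(interval = c(lower = lo, upper = hi), prediction = p_hat,
       threshold = thresh, level = level)
}
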