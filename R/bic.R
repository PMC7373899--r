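# Bayesian information criterion model selection across receptor-degradation
# variants (or any set of fits on one dataset).

#' Compare model fits by BIC
#'
#' `BIC = k * ln(n) - 2 * ln(L)`. The fits' `objective` values are taken as
#' `-2 ln L` up to one shared additive constant, which cancels in the
#' ranking.
#'
#' @param fits named list (one element per model/variant), each a list with
#'   `objective` (-2 log L at the optimum) and `k` (number of estimated
#'   parameters); a `n_data` element, if present, must agree across fits.
#' @param n_data number of data points underlying every fit.
#' @return data.frame (model, k, objective, bic, delta_bic) sorted ascending
#'   by BIC, with the winner first; attribute `winner`.
#' @export
compare_models <- function(fits, n_data) {
  stopifnot(length(fits) >= 2, !is.null(names(fits)), n_data >= 1)
  nd <- vapply(fits, function(f) f$n_data %||% n_data, 0)
  if (length(unique(nd)) != 1)
    stop("fits were computed on datasets of different size")
  k <- vapply(fits, `[[`, 0, "k")
  obj <- vapply(fits, `[[`, 0, "objective")
  bic <- k * log(n_data) + obj         # objective plays -2 log L
  out <- data.frame(model = names(fits), k = k, objective = obj, bic = bic)
  out <- out[order(out$bic), ]
  out$delta_bic <- out$bic - out$bic[1]
  rownames(out) <- NULL
  attr(out, "winner") <- out$model[1]
  out
}
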