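#' @useDynLib ifndyn, .registration = TRUE
#' @importFrom stats optimize rnorm runif setNames lm coef vcov uniroot
#'   pchisq qchisq pt median sd var quantile approx nlminb cor aggregate
#' @importFrom utils head tail read.csv write.csv
"_PACKAGE"

# ---- parameter bookkeeping -------------------------------------------------

#' Parameter classes of the estimation configuration
#'
#' Every estimated parameter carries one of three classes mirroring the model's
#' estimation setup: `"dynamic"` rate constants, `"initial"` basal abundances,
#' and `"scaling"` observation scale/offset parameters. All estimated
#' parameters live on the log10 scale; [parset()] validates positivity of the
#' implied natural-scale values by construction.
#'
#' @param pars named numeric vector of log10 parameters (a `ifndyn_parset`).
#' @return named character vector of classes, one per parameter.
#' @export
parameter_class <- function(pars) {
  nm <- names(pars)
  cls <- ifelse(nm %in% .dynamic_names, "dynamic",
         ifelse(nm %in% .initial_names, "initial",
         ifelse(nm %in% .scaling_names, "scaling", NA_character_)))
  names(cls) <- nm
  cls
}

#' Construct a full model parameter set (log10 scale)
#'
#' @param dynamic,initials,scalings named numeric vectors of log10 values for
#'   the three parameter classes. Offsets are stored as log10 of the natural
#'   offset (offsets are positive in the log-normal observation model).
#' @return an object of class `ifndyn_parset`: a named numeric log10 vector.
#' @export
parset <- function(dynamic, initials, scalings) {
  stopifnot(setequal(names(dynamic), .dynamic_names),
            setequal(names(initials), .initial_names),
            setequal(names(scalings), .scaling_names))
  x <- c(dynamic[.dynamic_names], initials[.initial_names],
         scalings[.scaling_names])
  stopifnot(all(is.finite(x)))
  structure(x, class = "ifndyn_parset")
}

#' Parameter counts of the estimation configuration
#'
#' Decomposes a parameter set into the counts exposed to the estimator:
#' initial abundances, observation scalings/offsets, and dynamic rate
#' constants.
#'
#' @param pars an `ifndyn_parset`.
#' @return named integer vector with elements `initials`, `scalings`,
#'   `dynamic`, `total`.
#' @export
parameter_counts <- function(pars) {
  cls <- parameter_class(pars)
  out <- c(initials = sum(cls == "initial", na.rm = TRUE),
           scalings = sum(cls == "scaling", na.rm = TRUE),
           dynamic  = sum(cls == "dynamic", na.rm = TRUE))
  c(out, total = sum(out))
}

#' Parameters eligible for cell-type ratio estimation
#'
#' The cell-type transfer estimates one log10 ratio per eligible parameter.
#' Eligible are the dynamic and initial parameters, excluding the four
#' abundance parameters that are freely re-estimated per cell type
#' (`totSTAT1`, `totSTAT2`, `totIRF9`, `synthUSP18`) and the four parameters
#' that only act in overexpression/inhibitor conditions. Observation
#' scalings/offsets are always re-estimated per cell type and are never ratio
#' parameters. `BindIFN` remains in the eligible set but its ratio is pinned
#' to zero by default during transfer fits (the ligand binding affinity is
#' fixed across cell types once estimated).
#'
#' @param pars an `ifndyn_parset`.
#' @return character vector of eligible parameter names.
#' @export
l1_eligible_parameters <- function(pars) {
  cls <- parameter_class(pars)
  pool <- names(pars)[cls %in% c("dynamic", "initial")]
  drop <- c("totSTAT1", "totSTAT2", "totIRF9", "synthUSP18",
            "synthUSP18mRNAbasal_OE", "synthUSP18_inh",
            "synthUSP18mRNAbasal_inh", "synthUSP18mRNA_inh")
  setdiff(pool, drop)
}

#' @export
print.ifndyn_parset <- function(x, ...) {
  cnt <- parameter_counts(x)
  cat("IFN signaling model parameter set (log10 scale)\n")
  cat(sprintf("  %d dynamic, %d initial, %d scaling/offset (total %d)\n",
              cnt["dynamic"], cnt["initials"], cnt["scalings"], cnt["total"]))
  invisible(x)
}
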