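# Steady-state parameter transform: basal synthesis rates (and the
# degradation rates of the four feedback proteins whose basal mRNA and
# protein abundances are both estimated) are not free parameters but are
# derived so that the unstimulated system is an exact fixed point at the
# specified basal abundances.

#' Natural-scale values of a log10 parameter set
#' @param pars an `ifndyn_parset` (log10 scale).
#' @return named numeric vector on natural scale.
#' @export
natural_scale <- function(pars) 10^unclass(pars)

#' Apply the steady-state parameter transform
#'
#' Derives, from a log10 parameter set, all quantities that the steady-state
#' constraint determines: the basal receptor synthesis rate, the seven basal
#' transcription rates, the degradation rates of USP18/SOCS1/SOCS3/IRF2
#' (whose basal mRNA and protein levels are both specified as initials), the
#' basal mRNA levels of STAT1/STAT2/IRF9 (implied by protein turnover), and
#' the full unstimulated steady-state vector. With ligand = 0 the returned
#' state is an exact fixed point of the model equations.
#'
#' @param pars an `ifndyn_parset`.
#' @param oe_baseline if `TRUE`, the constitutive USP18 overexpression term is
#'   treated as active already at baseline and the derived basal USP18
#'   transcription is reduced accordingly; a negative implied synthesis rate
#'   is rejected naming the offending species.
#' @return object of class `ifndyn_ss`: list with `pars`, `derived` (named
#'   natural-scale vector), `y0` (steady state, named), `oe_baseline`.
#' @export
apply_steady_state <- function(pars, oe_baseline = FALSE) {
  nat <- natural_scale(pars)
  if (any(nat[c("degRec", paste0("deg", .genes, "mRNA"),
                "degSTAT1", "degSTAT2", "degIRF9")] <= 0))
    stop("basal degradation rates must be positive")

  rho_m <- nat[["impMono"]] / nat[["expMono"]]
  rho_9 <- nat[["impIRF9"]] / nat[["expMono"]]
  S1c <- nat[["totSTAT1"]] / (1 + rho_m); S1n <- nat[["totSTAT1"]] - S1c
  S2c <- nat[["totSTAT2"]] / (1 + rho_m); S2n <- nat[["totSTAT2"]] - S2c
  I9c <- nat[["totIRF9"]] / (1 + rho_9);  I9n <- nat[["totIRF9"]] - I9c

  # basal mRNA levels implied by protein turnover of the shuttling proteins
  mS1 <- nat[["degSTAT1"]] * S1c / nat[["synthSTAT1"]]
  mS2 <- nat[["degSTAT2"]] * S2c / nat[["synthSTAT2"]]
  mI9 <- nat[["degIRF9"]] * I9c / nat[["synthIRF9"]]
  # degradation rates implied for the feedback proteins
  degU <- nat[["synthUSP18"]] * nat[["USP18mRNA_0"]] / nat[["USP18_0"]]
  degS1p <- nat[["synthSOCS1"]] * nat[["SOCS1mRNA_0"]] / nat[["SOCS1_0"]]
  degS3p <- nat[["synthSOCS3"]] * nat[["SOCS3mRNA_0"]] / nat[["SOCS3_0"]]
  degI2 <- nat[["synthIRF2"]] * nat[["IRF2mRNA_0"]] / nat[["IRF2_0"]]

  mrna0 <- c(STAT1 = mS1, STAT2 = mS2, IRF9 = mI9,
             IRF2 = nat[["IRF2mRNA_0"]], USP18 = nat[["USP18mRNA_0"]],
             SOCS1 = nat[["SOCS1mRNA_0"]], SOCS3 = nat[["SOCS3mRNA_0"]])
  basal <- nat[paste0("deg", .genes, "mRNA")] * mrna0[.genes]
  names(basal) <- paste0("synth", .genes, "mRNAbasal")
  if (oe_baseline) {
    basal[["synthUSP18mRNAbasal"]] <-
      basal[["synthUSP18mRNAbasal"]] - nat[["synthUSP18mRNAbasal_OE"]]
    if (basal[["synthUSP18mRNAbasal"]] < 0)
      stop("steady state impossible: negative implied basal synthesis for ",
           "species USP18mRNA under baseline overexpression")
  }

  derived <- c(synthRec = unname(nat[["degRec"]] * nat[["Rec0"]]), basal,
               degUSP18 = unname(degU), degSOCS1 = unname(degS1p),
               degSOCS3 = unname(degS3p), degIRF2 = unname(degI2))
  if (any(derived < 0))
    stop("steady state impossible: negative implied rate for ",
         names(derived)[which(derived < 0)[1]])

  y0 <- setNames(numeric(41), .state_names)
  y0["Rec"] <- nat[["Rec0"]]
  y0[c("STAT1c", "STAT1n", "STAT2c", "STAT2n", "IRF9c", "IRF9n")] <-
    c(S1c, S1n, S2c, S2n, I9c, I9n)
  y0[paste0(.genes, "mRNA")] <- mrna0[.genes]
  y0[c("USP18", "SOCS1", "SOCS3", "IRF2")] <-
    nat[c("USP18_0", "SOCS1_0", "SOCS3_0", "IRF2_0")]
  for (g in .genes) y0[paste0(g, c("ch1", "ch2"))] <- mrna0[[g]]

  structure(list(pars = pars, nat = nat, derived = derived, y0 = y0,
                 oe_baseline = oe_baseline),
            class = "ifndyn_ss")
}

# Assemble the compiled-RHS parameter vector for a steady-state-transformed
# parameter set under a given condition/variant (IFN slot set per segment).
.c_parms <- function(ss, variant, knockdown_factor = 1, overexpression = FALSE) {
  nat <- ss$nat
  p <- setNames(numeric(length(.c_parm_names)), .c_parm_names)
  struct <- .dynamic_names[1:53]
  p[struct] <- nat[struct]
  p[c("VdegUSP18", "KmdegUSP18")] <- 0
  if (variant == "USP18") {
    # the USP18-only variant reuses the Vmax/Km slots of the (absent)
    # SOCS1-mediated reaction as its own enzymatic constants
    p["VdegUSP18"] <- nat[["VdegSOCS1"]]
    p["KmdegUSP18"] <- nat[["KmdegSOCS1"]]
  }
  p[names(ss$derived)] <- ss$derived
  p["swSOCS1deg"] <- as.numeric(variant %in% c("SOCS1", "SOCS1_or_SOCS1xUSP18"))
  p["swUSP18deg"] <- as.numeric(variant == "USP18")
  p["swCoop"] <- as.numeric(variant %in% c("SOCS1xUSP18", "SOCS1_or_SOCS1xUSP18"))
  p["kdUSP18"] <- knockdown_factor
  p["swOE"] <- as.numeric(overexpression)
  p["IFN"] <- 0
  p
}
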