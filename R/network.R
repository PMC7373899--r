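# Reaction-network representation of the IFNalpha signaling model.
#
# The network object is the authoritative structural description (species,
# reactions, rate-law kinds, modifiers, stoichiometry); simulation itself runs
# through a compiled superset RHS in which the receptor-degradation variants
# are selected by switch parameters. Consistency between the two
# representations is covered by the steady-state and conservation tests.

.variants <- c("SOCS1", "USP18", "SOCS1xUSP18", "SOCS1_or_SOCS1xUSP18")

.protein_of <- c(STAT1 = "STAT1c", STAT2 = "STAT2c", IRF9 = "IRF9c",
                 IRF2 = "IRF2", USP18 = "USP18", SOCS1 = "SOCS1",
                 SOCS3 = "SOCS3")

.rxn <- function(id, rate_law, rate, reactants = NULL, products = NULL,
                 modifiers = character()) {
  list(id = id, rate_law = rate_law, rate = rate,
       reactants = reactants, products = products, modifiers = modifiers)
}

#' Build the IFN signal-transduction reaction network
#'
#' Constructs the species and reaction lists for one of the four
#' receptor-degradation variants: degradation of the activated
#' receptor-ligand complex mediated enzymatically by SOCS1 alone, by USP18
#' alone, by the cooperative SOCS1:USP18 pair alone, or by SOCS1 and the
#' cooperative pair as two separate enzymatic reactions (the selected model).
#' With the deposited two-step translation delay chains the selected variant
#' has 41 species and 75 reactions.
#'
#' @param variant one of `"SOCS1"`, `"USP18"`, `"SOCS1xUSP18"`,
#'   `"SOCS1_or_SOCS1xUSP18"`.
#' @param chain_steps named integer vector of delay-chain lengths per gene
#'   (names `STAT1`, `STAT2`, `IRF9`, `IRF2`, `USP18`, `SOCS1`, `SOCS3`);
#'   defaults to the deposited configuration of 2 steps per gene.
#' @return an object of class `ifndyn_network` with elements `species`
#'   (data.frame: name, compartment, role), `reactions` (list), `variant`,
#'   `chain_steps`.
#' @export
build_network <- function(variant = "SOCS1_or_SOCS1xUSP18",
                          chain_steps = setNames(rep(2L, 7), .genes)) {
  if (!variant %in% .variants)
    stop("unknown receptor variant: ", variant)
  chain_steps <- chain_steps[.genes]
  if (any(is.na(chain_steps)) || any(chain_steps < 1L))
    stop("delay chain lengths must be >= 1 for every gene")

  species <- data.frame(
    name = c("Rec", "aRecIFN",
             "STAT1c", "STAT1n", "STAT2c", "STAT2n", "IRF9c", "IRF9n",
             "pSTAT1dimc", "pSTAT1dimn", "pSTAT1pSTAT2c", "pSTAT1pSTAT2n",
             "ISGF3c", "ISGF3n", "OccGASbs", "OccGISREbs",
             paste0(.genes, "mRNA"), "USP18", "SOCS1", "SOCS3", "IRF2"),
    compartment = c("membrane", "membrane",
                    rep(c("cytoplasm", "nucleus"), 6),
                    "promoter", "promoter",
                    rep("cytoplasm", 7), rep("cytoplasm", 4)),
    role = c("receptor", "receptor",
             rep("transcription_factor", 12),
             "occupancy", "occupancy",
             rep("mRNA", 7), rep("protein", 4)),
    stringsAsFactors = FALSE)
  for (g in .genes) {
    k <- chain_steps[[g]]
    species <- rbind(species, data.frame(
      name = paste0(g, "ch", seq_len(k)),
      compartment = "cytoplasm", role = "chain_intermediate",
      stringsAsFactors = FALSE))
  }
  stopifnot(!anyDuplicated(species$name))

  fU <- "/(1+USP18/KiUSP18)"
  den <- "/(1+STAT1c/KmactSTAT1+STAT2c/KmactSTAT2)"
  rx <- list(
    .rxn("synth_Rec", "mass_action", "synthRec", products = c(Rec = 1)),
    .rxn("deg_Rec", "mass_action", "degRec*Rec", reactants = c(Rec = 1)),
    .rxn("act_Rec", "inhibited_mass_action",
         "BindIFN*IFN*Rec/(1+(SOCS1+SOCS3)/KiSOCS)",
         reactants = c(Rec = 1), products = c(aRecIFN = 1),
         modifiers = c("SOCS1", "SOCS3")),
    .rxn("recyc_aRec", "mass_action", "recycRec*aRecIFN",
         reactants = c(aRecIFN = 1), products = c(Rec = 1)))
  if (variant %in% c("SOCS1", "SOCS1_or_SOCS1xUSP18"))
    rx <- c(rx, list(.rxn("deg_aRec_SOCS1", "michaelis_menten",
      "VdegSOCS1*SOCS1/(KmdegSOCS1+SOCS1)*aRecIFN",
      reactants = c(aRecIFN = 1), modifiers = "SOCS1")))
  if (variant == "USP18")
    rx <- c(rx, list(.rxn("deg_aRec_USP18", "michaelis_menten",
      "VdegUSP18*USP18/(KmdegUSP18+USP18)*aRecIFN",
      reactants = c(aRecIFN = 1), modifiers = "USP18")))
  if (variant %in% c("SOCS1xUSP18", "SOCS1_or_SOCS1xUSP18"))
    rx <- c(rx, list(.rxn("deg_aRec_SOCS1xUSP18", "michaelis_menten",
      "VdegCoop*(SOCS1/(KmdegCoop+SOCS1))*(USP18/(KmdegCoop+USP18))*aRecIFN",
      reactants = c(aRecIFN = 1), modifiers = c("SOCS1", "USP18"))))

  rx <- c(rx, list(
    .rxn("act_STAT1dim", "inhibited_mass_action",
         paste0("actSTAT1*aRecIFN*STAT1c^2", fU, den),
         reactants = c(STAT1c = 2), products = c(pSTAT1dimc = 1),
         modifiers = c("aRecIFN", "USP18")),
    .rxn("act_STAT1STAT2", "inhibited_mass_action",
         paste0("actSTAT12*aRecIFN*STAT1c*STAT2c", fU, den),
         reactants = c(STAT1c = 1, STAT2c = 1),
         products = c(pSTAT1pSTAT2c = 1), modifiers = c("aRecIFN", "USP18")),
    .rxn("form_ISGF3", "mass_action", "formISGF3*pSTAT1pSTAT2c*IRF9c",
         reactants = c(pSTAT1pSTAT2c = 1, IRF9c = 1),
         products = c(ISGF3c = 1)),
    .rxn("imp_pSTAT1dim", "mass_action", "impComplex*pSTAT1dimc",
         reactants = c(pSTAT1dimc = 1), products = c(pSTAT1dimn = 1)),
    .rxn("imp_pSTAT1pSTAT2", "mass_action", "impComplex*pSTAT1pSTAT2c",
         reactants = c(pSTAT1pSTAT2c = 1), products = c(pSTAT1pSTAT2n = 1)),
    .rxn("imp_ISGF3", "mass_action", "impComplex*ISGF3c",
         reactants = c(ISGF3c = 1), products = c(ISGF3n = 1)),
    .rxn("diss_pSTAT1dim", "mass_action", "dissSTAT*pSTAT1dimn",
         reactants = c(pSTAT1dimn = 1), products = c(STAT1n = 2)),
    .rxn("diss_pSTAT1pSTAT2", "mass_action", "dissSTAT*pSTAT1pSTAT2n",
         reactants = c(pSTAT1pSTAT2n = 1),
         products = c(STAT1n = 1, STAT2n = 1)),
    .rxn("diss_ISGF3", "mass_action", "dissISGF3*ISGF3n",
         reactants = c(ISGF3n = 1),
         products = c(STAT1n = 1, STAT2n = 1, IRF9n = 1)),
    .rxn("imp_STAT1", "mass_action", "impMono*STAT1c",
         reactants = c(STAT1c = 1), products = c(STAT1n = 1)),
    .rxn("exp_STAT1", "mass_action", "expMono*STAT1n",
         reactants = c(STAT1n = 1), products = c(STAT1c = 1)),
    .rxn("imp_STAT2", "mass_action", "impMono*STAT2c",
         reactants = c(STAT2c = 1), products = c(STAT2n = 1)),
    .rxn("exp_STAT2", "mass_action", "expMono*STAT2n",
         reactants = c(STAT2n = 1), products = c(STAT2c = 1)),
    .rxn("imp_IRF9", "mass_action", "impIRF9*IRF9c",
         reactants = c(IRF9c = 1), products = c(IRF9n = 1)),
    .rxn("exp_IRF9", "mass_action", "expMono*IRF9n",
         reactants = c(IRF9n = 1), products = c(IRF9c = 1)),
    .rxn("bind_GAS", "hill_saturation", "bindGAS*pSTAT1dimn/(KmGAS+pSTAT1dimn)",
         products = c(OccGASbs = 1), modifiers = "pSTAT1dimn"),
    .rxn("off_GAS", "mass_action", "offGAS*OccGASbs",
         reactants = c(OccGASbs = 1)),
    .rxn("bind_ISRE_het", "hill_saturation",
         "bindISREhet*pSTAT1pSTAT2n/(KmISRE+pSTAT1pSTAT2n)",
         products = c(OccGISREbs = 1), modifiers = "pSTAT1pSTAT2n"),
    .rxn("bind_ISRE_ISGF3", "hill_saturation",
         "bindISREisgf3*ISGF3n/(KmISRE+ISGF3n)",
         products = c(OccGISREbs = 1), modifiers = "ISGF3n"),
    .rxn("off_ISRE", "mass_action", "offISRE*OccGISREbs",
         reactants = c(OccGISREbs = 1))))

  for (g in .genes) {
    m <- paste0(g, "mRNA")
    driver <- if (g == "SOCS3") "OccGASbs" else "OccGISREbs"
    ind_rate <- paste0("synth", g, "mRNA*", driver)
    ind_mod <- driver
    if (g == "USP18") ind_rate <- paste0(ind_rate, "^3")
    if (g == "SOCS1") {
      ind_rate <- paste0(ind_rate, "/(1+IRF2/KiIRF2)")
      ind_mod <- c(ind_mod, "IRF2")
    }
    k <- chain_steps[[g]]
    chain <- paste0(g, "ch", seq_len(k))
    tr <- list(
      .rxn(paste0("synth_", m, "_basal"), "mass_action",
           paste0("synth", g, "mRNAbasal"), products = setNames(1, m)),
      .rxn(paste0("synth_", m, "_induced"), "hill_saturation", ind_rate,
           products = setNames(1, m), modifiers = ind_mod),
      .rxn(paste0("deg_", m), "mass_action", paste0("deg", g, "mRNA*", m),
           reactants = setNames(1, m)),
      .rxn(paste0("transl_init_", g), "mass_action",
           paste0("synth", g, "*", m),
           products = setNames(1, chain[1]), modifiers = m))
    if (k > 1) for (i in seq_len(k - 1))
      tr <- c(tr, list(.rxn(paste0("transl_step_", g, "_", i), "mass_action",
        paste0("synth", g, "*", chain[i]),
        reactants = setNames(1, chain[i]),
        products = setNames(1, chain[i + 1]))))
    tr <- c(tr, list(.rxn(paste0("transl_exit_", g), "mass_action",
      paste0("synth", g, "*", chain[k]),
      reactants = setNames(1, chain[k]),
      products = setNames(1, .protein_of[[g]]))))
    rx <- c(rx, tr)
  }
  for (g in .genes) {
    pr <- .protein_of[[g]]
    rx <- c(rx, list(.rxn(paste0("deg_", pr), "mass_action",
      paste0("deg", g, "*", pr), reactants = setNames(1, pr))))
  }

  ids <- vapply(rx, `[[`, "", "id")
  stopifnot(!anyDuplicated(ids))
  structure(list(species = species, reactions = rx, variant = variant,
                 chain_steps = chain_steps),
            class = "ifndyn_network")
}

#' @export
print.ifndyn_network <- function(x, ...) {
  cat(sprintf("IFN signaling network, variant %s: %d species, %d reactions\n",
              x$variant, nrow(x$species), length(x$reactions)))
  invisible(x)
}

#' Stoichiometry matrix of a network
#'
#' @param network an `ifndyn_network`.
#' @return integer matrix (species x reactions); modifiers contribute zero.
#' @export
stoichiometry_matrix <- function(network) {
  sp <- network$species$name
  S <- matrix(0L, nrow = length(sp), ncol = length(network$reactions),
              dimnames = list(sp, vapply(network$reactions, `[[`, "", "id")))
  for (j in seq_along(network$reactions)) {
    r <- network$reactions[[j]]
    for (nm in names(r$reactants)) S[nm, j] <- S[nm, j] - r$reactants[[nm]]
    for (nm in names(r$products))  S[nm, j] <- S[nm, j] + r$products[[nm]]
  }
  S
}

#' Species and reaction counts
#' @param network an `ifndyn_network`.
#' @return named integer vector `c(species=, reactions=)`.
#' @export
network_counts <- function(network) {
  c(species = nrow(network$species), reactions = length(network$reactions))
}
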