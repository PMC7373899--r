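# Shared constants: gene list, parameter and state name vectors,
# compiled-RHS parameter order.

.genes <- c("STAT1", "STAT2", "IRF9", "IRF2", "USP18", "SOCS1", "SOCS3")

.dynamic_names <- c(
  # receptor module
  "BindIFN", "degRec", "recycRec", "KiSOCS",
  "VdegSOCS1", "KmdegSOCS1", "VdegCoop", "KmdegCoop",
  # lumped phosphorylation / complex formation (competitive receptor docking)
  "actSTAT1", "actSTAT12", "KmactSTAT1", "KmactSTAT2", "KiUSP18", "formISGF3",
  # nucleocytoplasmic transport
  "impComplex", "impMono", "impIRF9", "expMono",
  # nuclear complex dissociation
  "dissSTAT", "dissISGF3",
  # promoter occupancy
  "bindGAS", "KmGAS", "offGAS", "bindISREhet", "bindISREisgf3",
  "KmISRE", "offISRE",
  # degradation of the shuttling proteins
  "degSTAT1", "degSTAT2", "degIRF9",
  # induced transcription (Vmax per gene)
  paste0("synth", .genes, "mRNA"),
  "KiIRF2",
  # mRNA turnover
  paste0("deg", .genes, "mRNA"),
  # translation / delay-chain rates
  paste0("synth", .genes),
  # overexpression / inhibitor condition parameters
  "synthUSP18mRNAbasal_OE", "synthUSP18_inh",
  "synthUSP18mRNAbasal_inh", "synthUSP18mRNA_inh"
)

.initial_names <- c(
  "Rec0", "totSTAT1", "totSTAT2", "totIRF9",
  "USP18_0", "SOCS1_0", "SOCS3_0", "IRF2_0",
  "USP18mRNA_0", "SOCS1mRNA_0", "SOCS3mRNA_0", "IRF2mRNA_0"
)

.scaling_names <- c(
  paste0("scale_", c("pSTAT1_Cyt", "pSTAT2_Cyt", "pSTAT1_Nuc", "pSTAT2_Nuc",
                     "tSTAT1_Cyt", "tSTAT1_Nuc", "tSTAT2_Cyt", "tSTAT2_Nuc",
                     "IRF9_Cyt", "IRF9_Nuc", "USP18", "SOCS1", "SOCS3")),
  paste0("offset_", c("pSTAT1_Cyt", "pSTAT2_Cyt", "pSTAT1_Nuc", "pSTAT2_Nuc"))
)

# parameters handed to the compiled RHS, in C order (natural scale)
.c_parm_names <- c(
  "IFN",
  .dynamic_names[1:53],              # structural dynamic parameters + OE rate
  "VdegUSP18", "KmdegUSP18",         # receptor variant 'USP18' only
  "synthRec", paste0("synth", .genes, "mRNAbasal"),
  "degUSP18", "degSOCS1", "degSOCS3", "degIRF2",
  "swSOCS1deg", "swUSP18deg", "swCoop", "kdUSP18", "swOE"
)

.state_names <- c(
  "Rec", "aRecIFN", "STAT1c", "STAT1n", "STAT2c", "STAT2n",
  "IRF9c", "IRF9n", "pSTAT1dimc", "pSTAT1dimn",
  "pSTAT1pSTAT2c", "pSTAT1pSTAT2n", "ISGF3c", "ISGF3n",
  "OccGASbs", "OccGISREbs",
  paste0(.genes, "mRNA"),
  "USP18", "SOCS1", "SOCS3", "IRF2",
  as.vector(t(outer(.genes, c("ch1", "ch2"), paste0)))
)

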