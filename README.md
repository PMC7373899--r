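# ifndyn

Dynamic modeling of IFN-alpha-induced JAK/STAT signal transduction in
hepatocytes: an ODE pathway model with USP18/SOCS1/SOCS3/IRF2 feedback,
plus the complete calibration and analysis machinery around it.

## Who this is for

Systems biologists studying interferon refractoriness: why cells primed with
a high IFN-alpha dose respond weakly to restimulation (desensitization),
why low-dose priming can *enhance* the response (hypersensitization), and
which cellular factors predict a patient's antiviral response.

## What it implements

**The model.** A 41-species, 75-reaction ODE system: a lumped receptor
activated by ligand; lumped STAT1/STAT2 phosphorylation-dimerization with
competitive receptor docking; ISGF3 assembly; nucleocytoplasmic shuttling;
GAS and GAS/ISRE promoter occupancy driving seven feedback genes through
two-step translation delay chains (linear chain trick); USP18 inhibition of
STAT phosphorylation; SOCS1/SOCS3 inhibition of receptor activation; and
enzymatic degradation of the active receptor complex by SOCS1 and by the
cooperative SOCS1:USP18 pair. Four receptor-degradation variants are
selectable; all dynamics run through a compiled right-hand side with
stop-and-restart event handling.

**Calibration machinery.**

- combined scaling/error model for replicate immunoblots
  (log-normal signals, gel-specific scaling factors, 1-sigma CIs),
  spike-in molecules-per-cell calibration, and qRT-PCR normalization to the
  geometric mean of GAPDH/HPRT/TBP;
- maximum-likelihood objective (sum of squared standardized residuals,
  `-2 log L`) with a weak L2 prior on log10 parameters
  (`sum((log10 theta / 5)^2)`), multi-start optimization with waterfall
  output, sensitivity-based gradients, profile-likelihood identifiability,
  prediction profiles, and BIC model selection
  (`BIC = k ln n - 2 ln L`);
- elastic-net estimation of cell-type-specific log10 ratio parameters
  (`lambda (|delta| + delta^2)`, L1 = L2 at one decade) over the 60-member
  eligible set, with model size chosen by the modified criterion
  `4 ln(n) k - 2 ln L`;
- virtual patient cohort (log-normal patient-specific STAT1/STAT2/IRF9/USP18
  abundances and residual plasma IFN-alpha), antiviral-response metrics
  (baseline-subtracted AUC of occupied promoter sites, 24-28 h), and
  desensitization thresholds with Spearman correlation analysis;
- GAS (`TTNCNNNAA`) and ISRE (`TTTCNNTTYY`) consensus scanning of promoter
  sequences;
- a synthetic-data generator whose calibrated nominal truth reproduces the
  measured 1-h dose-response anchors and the priming phenotypes, and which
  emits immunoblot, qRT-PCR, calibration-curve and plasma fixtures with the
  statistical structure the analysis assumes.

## Worked example

```r
library(ifndyn)

net <- build_network("SOCS1_or_SOCS1xUSP18")
network_counts(net)
#>   species reactions
#>        41        75

pars <- nominal_parameters()        # calibrated generator truth, verified
round(attr(pars, "anchors"), 3)     # 1-h dose-response vs the 2,800 pM top
#>          2.8    28  1400 2800
#> pSTAT1 0.500 1.002 1.001    1
#> pSTAT2 0.102 0.564 0.991    1

# relative antiviral response (dAUC 24-28 h of occupied promoter sites,
# primed vs unprimed) across Roferon priming doses
sapply(c(1.2, 60, 608), function(d)
  antiviral_response(pars, prestim_dose = d, ligand = "Roferon",
                     grid_by = 0.1)$relative)
#>  1.2 pM  60 pM 608 pM
#>   1.177  0.198  0.015

desensitization_threshold(pars, dose_range = c(0.5, 200),
                          grid_by = 0.1)$threshold
#> 3.8   # pM Roferon: priming above this dose suppresses the response

calibrate_knockdown(pars, target_reduction = 0.945)
#> knockdown factor 0.0171 -> 94.5% USP18 reduction at 24 h of 1,400 pM
```

Reading the numbers: STAT1 phosphorylation after 1 h is half-maximal at
2.8 pM and saturated by 1,400 pM, while STAT2 phosphorylation is at 10% at
2.8 pM -- the two responses report different dose windows. Priming with
1.2 pM Roferon *raises* the subsequent antiviral response by ~18%
(hypersensitization); priming with 608 pM all but abolishes it; the
crossover (desensitization threshold) sits at ~4 pM Roferon. Scaling USP18
mRNA synthesis to 1.7% reproduces the measured 94.5% protein-level
knockdown.

The recovery studies run end to end on synthetic data:
`variant_selection_study()` refits all four receptor-degradation variants
and identifies the generating SOCS1 | SOCS1:USP18 structure by BIC;
`celltype_transfer_study("HepG2")` and `("PHH")` recover exactly 2 and 5
planted cell-type ratio parameters by the elastic net.

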