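Package: ifndyn
Title: Dynamic Modeling of Interferon-Alpha JAK/STAT Signal Transduction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordinary-differential-equation model of IFN-alpha-induced JAK/STAT
    signaling in hepatocytes with USP18, SOCS1, SOCS3 and IRF2 feedback, linear-chain
    translation delays and promoter-occupancy readouts, together with the calibration
    machinery needed to fit it: an immunoblot scaling/error model, maximum-likelihood
    multi-start estimation with weak L2 priors, profile-likelihood identifiability,
    BIC-based receptor-variant selection, elastic-net estimation of cell-type-specific
    parameter ratios, virtual-patient-cohort simulation of antiviral responses and
    desensitization thresholds, GAS/ISRE promoter motif scanning, and a synthetic-data
    generator emulating immunoblot, qRT-PCR, spike-in calibration and plasma-IFN data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    jsonlite,
    xml2,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
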