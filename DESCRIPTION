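Package: hepstat3
Title: Dynamic Modelling of IL-6-Induced JAK1-STAT3 Signalling in Hepatocytes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-compartment mass-action ODE model of IL-6-induced
    JAK1-STAT3 signalling in primary hepatocytes, with SOCS3 negative
    feedback, linear-chain transcriptional delays for Socs3 and seven
    acute-phase-protein genes, and pharmacology of the JAK inhibitor
    Ruxolitinib, the STAT3 inhibitor Stattic and actinomycin D.
    Includes maximum-likelihood calibration with multi-start
    optimization and profile-likelihood identifiability, local
    parameter sensitivity analysis of the integrated acute-phase
    response, Ruxolitinib repeated-dosing schedule design under a
    concentration cap, four-parameter logistic dose-response fitting
    and inversion for physiological IL-6 inference, and a synthetic
    data generator emulating the calibration experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    lhs,
    minpack.lm,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    Matrix,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
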