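Package: rnpinventory
Title: Absolute Quantification of Telomerase RNP Components and Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimators for counting telomerase components in human cells:
    absolute RNA copy number per cell by spike-in titration RT-qPCR, band
    quantification of northern and western blots against standard titrations
    (including detection-limit upper bounds), radiolabel bookkeeping for a
    35S-labeled protein standard, immunoprecipitation mass-balance estimation
    of assembled telomerase ribonucleoprotein and total hTERT per cell, direct
    telomerase extension assay quantification (nucleotides incorporated per
    enzyme per minute), and Michaelis-Menten kinetics for dGTP by
    Lineweaver-Burk and nonlinear least squares. A synthetic-data generator
    emulates every raw measurement type (qPCR Cq tables, blot densitometry,
    scintillation counts, IP fractionation, assay gels) from a known ground
    truth so that every estimator can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    seqinr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
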