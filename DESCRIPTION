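Package: psilac
Title: Protein Loss Kinetics and Synaptic Failure Analyses Under Protein
    Synthesis Inhibition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analyses of neuronal protein turnover and synaptic failure under
    acute protein synthesis inhibition. Implements a first-order kinetic model
    predicting residual protein fractions (and log2 H/M ratios) from protein
    half-lives under partial synthesis suppression; a dynamic-SILAC loss
    pipeline (peptide aggregation, normalization to long-lived reference
    proteins, stringent peptide/experiment filtering, volcano classification,
    model comparison, rank and annotation-group scoring, enrichment-term
    post-filtering); synapse-tenacity analysis of tracked fluorescence puncta
    (smoothing, per-cell normalization, R-squared decay over time intervals)
    together with Mexican-hat puncta detection and fixed-ROI measurement; and
    quantification procedures for functional assays (synthesis-suppression
    fold, FM dye destaining, viability counts, network spike rates,
    extracellular flux plates). Seeded synthetic-data generators produce every
    input with known ground truth for recovery and calibration tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
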