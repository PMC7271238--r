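Package: picramp
Title: Persistent Inward Current and Excitability Analysis for Spinal
    Motoneurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for intrinsic-excitability phenotyping of
    spinal motoneurons from slow-ramp patch-clamp protocols. Extracts
    persistent inward currents (PICs) from voltage bi-ramps by leak
    subtraction, input conductance and capacitance from voltage steps,
    frequency-current (F-I) gain from current bi-ramps, applies the
    standard cell-inclusion filters and a hypoexcitability
    classification, and performs the group-level inference (ANOVA, Tukey
    post hoc, Welch t from printed summaries, binned chi-square).
    Includes a ground-truthed conductance-model generator of synthetic
    voltage- and current-clamp recordings and soma-volume cohorts,
    soma-volume morphometry from labeled 3D stacks, and a noisy-OR
    protein-interaction bridge analysis between gene sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    graphics,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr,
    yaml
Config/testthat/edition: 3
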