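Package: dualpet
Title: Dual-Tracer Brain PET Kinetic Analysis and Longitudinal Regional Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of dynamic dual-tracer (FDG glucose and
    11C-acetoacetate) brain positron emission tomography. Implements Patlak
    graphical analysis to estimate regional tracer extraction rate constants,
    conversion to cerebral metabolic rates via plasma substrate concentration
    and the lumped constant, Mueller-Gartner MR-based partial-volume correction,
    atlas-based regional extraction, per-region longitudinal linear mixed models
    with Benjamini-Hochberg false discovery rate correction, and associations
    between brain energy metabolism, insulin resistance (HOMA-IR) and cognitive
    composite scores. Includes a synthetic-data layer (analytic plasma input
    functions, irreversible two-compartment tissue curves, digital phantoms and
    a simulated longitudinal aging cohort) so the full pipeline is testable
    without access to scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
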