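Package: combiscreen
Title: Cmax-Anchored Drug Screening Scores and Chou-Talalay Synergy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-throughput viability screens of
    patient-derived tumor cells. Normalizes plate-level viability to vehicle
    controls, computes trapezoidal area under the dose-response curve on a
    log10-concentration axis, and maps it to a 0-100 drug score anchored at
    theoretical full-kill and no-effect areas. Fits four-parameter logistic
    (Hill) curves and Chou median-effect models, computes Chou-Talalay
    combination indices with synergy classification, and ranks single drugs
    and drug combinations across sample panels. Includes the downstream
    expression computations used in such screens (fold-change/p-value DEG
    filter, max-min heatmap gene selection, average-linkage clustering, and
    2^-ddCt relative quantification with error propagation), and a synthetic
    screen generator with known ground truth (Hill single agents, Loewe
    combination responses with tunable interaction, planted differential
    expression and Ct shifts) so every stage is testable without external
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
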