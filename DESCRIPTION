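Package: loomlab
Title: Quantification of Looming-Escape Behaviour, Collicular Visual
    Responses, Slice Electrophysiology and Label-Free Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated analysis pipeline for closed-loop looming-escape
    experiments in mice and the accompanying cellular-level measurements.
    Provides seeded synthetic-data generators with known ground truth for
    every modality (tracked arena sessions with closed-loop stimulus
    triggering, laminar LFP/spiking recordings, whole-cell patch-clamp sweep
    sets, and peptidoform intensity matrices), plus the analysis stages that
    recover that ground truth: escape classification and reaction-time
    metrics, shelter-exit and occupancy statistics, current-source-density
    laminar alignment, spike-triggered-average receptive fields, direction
    selectivity, loom response metrics and a resampling-based responsiveness
    test, passive membrane and action-potential kinetics with
    dendrotoxin-sensitive current subtraction, best-flyer protein-group
    quantification with Levenberg-Marquardt renormalisation and moderated-t
    differential testing, and a normality-routed statistical layer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    limma,
    sva,
    emmeans,
    car,
    lmerTest,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
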