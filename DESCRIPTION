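Package: mwlfuse
Title: Intermediate-Fusion Multimodal Networks for Perceived Mental Workload
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for classifying perceived mental workload
    from synchronised multi-rate physiological recordings (galvanic skin
    response, photoplethysmography, functional near-infrared spectroscopy and
    eye tracking). Provides a workload-modulated synthetic session simulator,
    multi-stream recording I/O with clock de-jitter and drift auditing,
    marker-based segmentation into eight-second pre-action windows, individual
    and group labelling schemes on the unit interval, four intermediate-fusion
    network variants built from per-modality sub-networks fused through dense
    projections into a shared head with a single sigmoid output, training under
    mean-squared-error loss with a triangular one-cycle learning-rate policy,
    cross-validated hyperparameter search, and the full set of evaluation
    metrics (mean absolute label error, levels-of-workload conversion,
    within-level fractions, error histograms, nearest-label confusion matrices
    and chance baselines).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
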