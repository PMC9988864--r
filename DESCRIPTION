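Package: microsar
Title: Temporal Species-Area Relationships in Closed Microcosm Time Series
Version: 0.9.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for amplicon (ASV) feature-table time series from
    replicated closed microcosms of graded volume. Implements even-depth
    rarefaction and rare-taxon filtering, per-time-point semi-logarithmic
    species-area relationship (SAR) fitting and occurrence summaries, local
    extinction and whole-microcosm annihilation statistics with
    extinction-volume correlation scans and mass-extinction detection,
    bell-form regression of pH and annihilation trajectories with successional
    phase segmentation, alpha/beta-diversity phase diagnostics, and
    trait-stratified extinction analyses. Ships a mechanistic stochastic
    community simulator (shared species pool, volume-dependent extinction
    hazards, pH-driven selective mass extinction, late resource collapse,
    whole-flask annihilation, sequencing subsampling) used for calibration
    and power evaluation of the analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    biomformat,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
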