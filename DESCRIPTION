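Package: discT2
Title: Lumbar Intervertebral Disc T2 Relaxometry with Long-Term Reliability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative T2 mapping of the lumbar intervertebral disc from
    multi-echo spin-echo sagittal MRI, together with the statistics needed to
    judge its long-term test-retest reliability. Provides a synthetic
    multi-echo spine phantom with full ground truth, semi-automated disc
    segmentation (vertical median filtering, spine-centre location, endplate
    seed detection and contour tracking, graph-search boundary refinement,
    anterior/posterior border detection), ellipse-based partitioning of each
    disc into five anterior-to-posterior subregions, mono-exponential T2
    estimation from 16-echo decay curves, and a complete reliability suite:
    one-way random-effects ICC(1,1) with exact F-based confidence intervals,
    standard error of measurement, minimum detectable difference,
    within-subject coefficients of variation, Bland-Altman agreement analysis
    with false-discovery-rate control, and between-session correlation
    matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    minpack.lm,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
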