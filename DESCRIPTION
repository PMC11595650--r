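Package: qseamorph
Title: Quantitative Standardized Expansion Assay for Blastocyst Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of blastocyst expansion dynamics
    from labeled time-lapse segmentation masks. Computes cross-sectional
    morphometric features at the median focal plane (embryo-plus-zona area,
    embryo-proper area, inner-cell-mass area, ICM/trophectoderm ratio, and
    zona pellucida thickness as the largest edge-to-edge distance), samples
    them on the standardized 30-minute grid over the five hours following
    blastulation (the quantitative Standardized Expansion Assay, qSEA),
    builds group-level expansion maps with per-timepoint normality-gated
    tests, and runs intra-cohort embryo ranking simulations comparing
    qSEA-based prioritization against Gardner-grade morphology. A calibrated
    synthetic cohort generator renders labeled masks with known geometry so
    the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff
Suggests:
    pROC,
    optparse,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
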