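Package: cxraeration
Title: Computerized Chest Radiograph Analysis of Neonatal Lung Aeration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies regional lung aeration on neonatal chest
    radiographs. Images are normalized to a liver intensity reference and
    to a common spatial scale via an annotated scale bar, then mean pixel
    intensity (MPI) and focal heterogeneity in pixel intensity (FHPI) are
    measured in twelve intercostal-segment regions of interest per image.
    Per-lung heterogeneity summaries, apico-basal gradient fits and a
    group-comparison statistical battery (Welch t, Fisher exact, Pearson
    correlation, repeated-measures ANOVA with Bonferroni post hoc,
    Friedman with Conover post hoc) are provided, together with a
    synthetic phantom generator with known ground truth for validating
    the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    png,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
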