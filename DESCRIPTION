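Package: trogomech
Title: Quantitative Analysis of Macrophage Trogocytosis Versus Phagocytosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the decision between trogocytosis
    (membrane "nibbling") and phagocytosis (complete engulfment) by
    macrophages challenged with antibody-opsonized target cells or giant
    unilamellar vesicles. Implements three-channel flow-cytometry gating
    and efficiency calculations, Young-Laplace estimation of cortical or
    membrane tension from micropipette aspiration, MESF bead calibration
    of antibody surface density, sigmoid dose-response fitting with
    bootstrap confidence intervals for the critical antibody density, and
    a mechanical scaling model that predicts a phase diagram of macrophage
    behaviour over target tension and antibody density. A seeded synthetic
    data module emulates the statistical structure of each assay so the
    full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
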