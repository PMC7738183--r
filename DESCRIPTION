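Package: granuleFusion
Title: Simulation and Analysis of Insulin Granule Subpopulation Fusion,
    Sizing and Composition
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates and analyses single-granule experiments that
    distinguish two subpopulations of insulin secretory granules defined by
    their synaptotagmin calcium sensor (syt7 or syt9). Provides seeded
    generators for TIRF fusion assays, FCS correlation runs, diameter
    samples, lipidomics tables, immunodepletion blots and secretion
    measurements; single-event photometry with a two-step content-release
    model; calcium dose-response Hill mixture decomposition; FCS
    hydrodynamic sizing with Vogel viscosity correction and the
    Stokes-Einstein relation; Gaussian mixture diameter analysis; and the
    associated tabular statistics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    minpack.lm,
    withr,
    yaml,
    jsonlite,
    tiff,
    SummarizedExperiment,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    mclust,
    EBImage
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
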