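Package: voimp
Title: Value of Implementation Analysis with Varying Marginal Costs and Benefits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for valuing strategies that increase the uptake of
    cost-effective health technologies when the per-patient incremental
    costs and benefits themselves depend on the implementation level
    (returns to scale). Provides implementation-dependent marginal
    cost/benefit profiles and the net monetary benefit they induce, an
    ordinary-least-squares meta-model that converts decision-model
    outputs into a linear net-monetary-benefit function of the
    implementation level, a break-even implementation solver, static
    (single-period) and dynamic (multi-year, discounted, diffusing)
    value-of-implementation calculations, and a packaged MammaPrint
    case study. Declarative YAML/JSON scenario configuration, tabular
    CSV/JSON writers, plotting and a small command-line interface are
    included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
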