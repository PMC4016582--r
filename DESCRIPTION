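Package: sizecontrol
Title: Sizer and Timer Models of Bacterial Cell Division
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to discriminate between age-dependent ("timer") and
    size-dependent ("sizer") control of bacterial cell division from
    single-cell lineage data. Provides an exact stochastic simulator of
    growing and dividing cell lineages (full genealogical trees and
    mother-machine style sparse trees) with phenotypic and measurement
    noise, single-cell growth-law characterization, nonparametric kernel
    estimation of age- and size-indexed division rates, upwind
    finite-volume solvers for the structured-population growth-fragmentation
    equations (age, size, and joint age-size models, including extensions
    with growth-rate variability and noisy septum positioning), and a
    normalized integrated-squared-error goodness-of-fit pipeline that
    reconstructs stable age-size distributions and selects the control
    model best supported by the data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'division-rate.R'
    'growth-law.R'
    'presets.R'
    'simulate.R'
    'cycles.R'
    'density-grid.R'
    'distance.R'
    'kde.R'
    'growth-analysis.R'
    'io.R'
    'measurement.R'
    'rate-estimation.R'
    'pde.R'
    'model-selection.R'
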