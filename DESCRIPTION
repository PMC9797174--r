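Package: rtspc
Title: Statistical Process Control for Automated Radiotherapy Plan QA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring automated radiotherapy treatment planning
    with statistical process control. Computes per-structure mean doses from
    dose grids and planar contour sets, forms percent mean-dose differences
    between a reference (autoplanned) calculation and a locally recalculated
    plan, builds per-contour individual control charts with 3-sigma limits and
    iterative outlier-excluded estimation of the chart mean and standard
    deviation, flags out-of-control cases, and characterizes the linear
    response of chart statistics to machine-model parameters (dosimetric leaf
    gap, MLC transmission factor) including normalized rates of change and
    zero-crossing estimates. Includes seeded synthetic cohort and parameter
    sweep generators so every stage is testable without clinical data, and a
    command-line interface for routine QA runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
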