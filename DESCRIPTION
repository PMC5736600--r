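Package: forestsink
Title: Long-Term Forest Plot Biomass Dynamics, Edge Effects and Drought Impacts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating above-ground live biomass (AGB) trajectories
    and carbon dynamics from long-term tropical forest census plots. Implements
    tree-level quality control of diameter series across point-of-measurement
    changes, height-diameter model fitting and selection, wood-density
    assignment by taxonomic hierarchy, per-interval wood productivity and
    biomass mortality with census-interval corrections for unobserved recruits
    and growth of dying trees, stem turnover rates with interval-length
    correction, change-point (hockey-stick) and asymptotic models of edge
    effects with bootstrap confidence intervals, linear mixed-effects trend
    estimation with a power variance function, drought-window contrasts, and
    carbon/regional scaling arithmetic. Includes a stand-demography simulator
    producing tree-by-tree census data with exportable ground truth for
    validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    nlme,
    minpack.lm,
    stats,
    utils
Suggests:
    boot,
    jsonlite,
    withr,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
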