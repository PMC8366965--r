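Package: damcba
Title: Cost-Benefit Analysis of Renovating Farm Dams for Livestock Water Quality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for appraising the renovation of farm dams (fencing,
    hardened watering points, revegetation) to improve livestock drinking
    water quality on beef cattle farms in south-eastern Australia. Implements
    a deterministic 50-year real-dollar discounted cash-flow model of per-farm
    benefits (additional steer weight gain, fertiliser savings, reduced
    desilting frequency) and costs (per-dam capital works and maintenance),
    break-even weight-gain analysis, sector-level aggregation, and a Monte
    Carlo uncertainty simulation over hypothetical farms with stochastic
    weight gain, a lognormal random-walk price model and year-scenario
    sampling of farm characteristics. Ships the published input tables as
    editable fixtures together with synthetic-data generators for price
    histories and farm populations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
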