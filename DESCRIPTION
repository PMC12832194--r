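Package: droughtGreen
Title: Drought Event Detection and Vegetation Greenness Response Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying vegetation greenness responses to
    meteorological drought in monsoon karst landscapes. Computes the
    6-month Standardized Precipitation-Evapotranspiration Index (SPEI-6)
    from monthly station climate via Thornthwaite potential
    evapotranspiration and an L-moment (probability-weighted moment)
    log-logistic standardization, identifies drought events by run theory
    with gap merging and minimum-duration rules, converts 16-day NDVI
    composites to monthly maximum-value composites, computes absolute and
    percent anomalies against drought-month-excluded monthly baselines,
    stratifies responses by vegetation type and karst versus non-karst
    landform, interpolates station fields to a grid by inverse-distance
    weighting or ordinary kriging, and generates fully seeded synthetic
    station climate, NDVI stacks, hydrothermal grids and categorical masks
    with planted drought episodes so that every pipeline stage is testable
    without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
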