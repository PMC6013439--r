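Package: tidalcarbon
Title: Tidal Wetland Soil Carbon Stock Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for converting tidal-wetland soil-core depth profiles into
    standardized carbon densities and national-scale carbon stocks. Implements
    the ideal mixing model of bulk density on organic matter (self-packing
    densities k1, k2) and the derived organic-matter-density model, a
    loss-on-ignition to organic-carbon quadratic conversion, depth-weighted
    aggregation of core profiles to 10-cm increments, segmented-regression
    detection of an organic/mineral soil threshold, random-intercept mixed
    models of carbon density with AICc multimodel inference, target-diagram
    skill metrics (normalized bias, unbiased RMSE), weighted aggregation and
    bias correction of soil-survey map units, and total-stock accounting.
    Includes a synthetic-data generator emulating the statistical structure of
    a national soil-core synthesis so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    minpack.lm,
    MASS,
    car,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
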