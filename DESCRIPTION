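Package: pbfate
Title: Long-Term Fate of Lead in Agricultural Soil and Dietary Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic first-order mass-balance simulator for lead (Pb)
    accumulation in the plough layer of agricultural soil under constant
    areal inputs (atmospheric deposition, fertilizer, gunshot), coupled to a
    soil-to-plant transfer model, dietary exposure assessment for adult
    vegetarians and children, and risk characterization against benchmark-
    dose-derived tolerable daily intakes (margins of safety and exposure,
    critical soil concentrations, time-to-critical inversion, maximum
    permissible input). Scenario parameterizations are read from structured
    configuration files; a built-in set of German farming scenarios is
    included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
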