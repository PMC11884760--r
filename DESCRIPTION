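Package: thermoscape
Title: Thermal Landscapes of Invaded Habitats for Small Ectotherms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how vegetation change reshapes the thermal
    landscapes available to small terrestrial ectotherms. Implements a
    pipeline from hourly operative-temperature logger series and
    righting-response trials to thermal-performance-curve traits (optimal
    temperature, peak performance, the B80 suitability breadth), thermal
    landscape composition, spatial heterogeneity and habitat-quality
    metrics, the buffering/amplifying "modifying capacity" of microsites
    relative to air temperature, and habitat-by-season mixed-model
    contrasts. Includes a synthetic microclimate and trial generator with
    known ground truth so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    lme4,
    lmerTest,
    emmeans,
    minpack.lm,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
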