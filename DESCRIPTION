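Package: washsim
Title: Simulation of WASH-Related Mortality, Water Access and Economic Losses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Country-level simulation of access to improved and piped water,
    WASH-attributable mortality and deaths, household water-collection time,
    and the associated economic losses (mortality and morbidity valued by a
    value-of-statistical-life benefit transfer; collection time valued at an
    opportunity cost of time). Semi-elasticities are estimated from
    country-year panels by pooled least squares with country-clustered
    standard errors, then propagated through annual forward recursions to a
    configurable horizon. Includes a synthetic-panel generator with known
    elasticities for validation, Monte Carlo uncertainty propagation with
    interquartile summaries and a variance decomposition based on squared
    standardized regression coefficients, and classification of countries
    into mortality-trajectory groups with population-weighted aggregation.
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
    sandwich
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
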