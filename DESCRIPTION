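Package: benthicflux
Title: Benthic Chamber Greenhouse-Gas Fluxes and Community Metabolism
Version: 0.1.0
Authors@R: person("Field", "Biogeochem Lab", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing static benthic-chamber incubations over
    coastal sediments: fits linear gas-accumulation slopes in the chamber
    headspace and converts them to areal CO2 and CH4 fluxes via the ideal
    gas law, derives hourly and daily community metabolism (community
    respiration, net community production, gross primary production) from
    dark/light dissolved-oxygen changes, classifies trophic status,
    expresses CH4 emissions as CO2 equivalents using a sustained-flux
    global warming potential, and compares replicate chambers across areas
    and sampling times with one-way ANOVA and Tukey HSD. A forward
    simulator generates chamber deployments with known ground truth so the
    whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
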