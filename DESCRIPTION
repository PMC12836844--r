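Package: afforest3PG
Title: Process-Based Simulation of Boreal Afforestation Scenarios with 3-PG
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Monthly process-based stand growth simulation (3-PG: Physiological
    Principles Predicting Growth) with adaptations for deciduous phenology, and a
    landscape pipeline for comparing coniferous versus deciduous afforestation
    strategies in the boreal under future climate scenarios. Includes a synthetic
    landscape generator (climate normals per emissions pathway, landcover, soil
    organic carbon, elevation), site preparation (soil-carbon derived fertility,
    topographic-wetness derived soil water capacity, planting eligibility),
    wetness-stratified planting rules, a scenario runner over a planting-rule by
    climate-scenario grid, and nonparametric post-hoc analysis of the resulting
    biomass and water-stress distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
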