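Package: keyhabitat
Title: Key-Habitat Delineation from Presence-Only Occurrence Models and
    Vegetation-Index Degradation
Version: 0.1.0
Authors@R:
    person("Key Habitat", "Maintainers", email = "maintainers@keyhabitat.org",
           role = c("aut", "cre"))
Description: A pipeline for identifying key habitats for threatened species:
    delineates a study area from environmental raster layers, fits a
    presence-only occurrence model by maximum likelihood with replicated
    calibration/validation and AICc model selection, quantifies vegetation
    degradation from 16-day EVI time series with a single change point in
    mean and variance, classifies current habitat suitability from EVI
    phenology with a bagged-tree ordinal classifier, and intersects historic
    occurrence with current suitability to compute Area of Occupancy
    decline and an IUCN A2 threat category. Includes a synthetic-landscape
    generator so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
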