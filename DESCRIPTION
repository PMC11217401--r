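Package: kelpcarbon
Title: Regional Climate-Benefit Modelling for Kelp Aquaculture
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic and Monte Carlo evaluation of the climate benefits
    of temperate kelp (seaweed) farming at regional scale. The model chains
    harvested biomass, back-calculated net primary production and detrital
    carbon export to marine sequestration pathways (passive detrital burial,
    near-farm release, active deep-water sinking), avoided emissions from
    seaweed-based products replacing conventional food, animal feed and
    biofuel, and the industry's own emission terms (nursery, capital,
    transport, maintenance, sinking, harvest transport and processing).
    Includes scenario configuration, zonal area-weighting of spatially
    varying parameters, uncertainty propagation from per-parameter sampling
    distributions, one-at-a-time sensitivity analysis at sub-model and
    parameter resolution, and a techno-economic assessment of cost per unit
    climate benefit.
License: MIT + file LICENSE
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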