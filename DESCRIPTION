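Package: realTPC
Title: Realised Thermal Performance Curves in a Bioenergetic Fish Community Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An individual-based, spatially explicit bioenergetic model of a
    size-structured fish community, built to study how realised thermal
    performance curves (TPCs) of net energy diverge from fundamental ones when
    food availability and dissolved oxygen covary with temperature. Provides a
    synthetic gridded forcing generator (temperature, oxygen saturation,
    low-trophic-level prey biomass), individual-level energy fluxes (Holling
    type I ingestion, oxygen dose-response and Arrhenius-type temperature
    responses of energy mobilisation and maintenance), calibration of species
    thermal responses to prescribed characteristic points (Tmin, Topt, Tmax),
    a multispecies school-based simulator with opportunistic size-based
    predation, and an analysis pipeline that quantifies the deviation of
    realised from fundamental TPCs and decomposes it into food-limitation and
    oxygen-limitation components per species and life stage, including trophic
    level estimation from simulated diets and an ANCOVA of the food component
    on trophic level by life stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Collate:
    'constants.R'
    'AllClasses.R'
    'grid.R'
    'forcing.R'
    'species.R'
    'bioenergetics.R'
    'calibrate.R'
    'sim.R'
    'tpc.R'
    'trophic.R'
    'config.R'
    'runall.R'
    'plot.R'
    'realTPC-package.R'
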