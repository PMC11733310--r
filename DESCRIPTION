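Package: batscape
Title: Radar-Based Bat Foraging Activity Surfaces and Prey Association Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for turning per-scan weather-radar bat presence rasters
    into seasonal foraging-activity surfaces, correcting them for
    roost-commute inflation with an exponential distance-decay factor,
    computing area-weighted land-cover foraging statistics with bootstrap
    confidence intervals, deriving a temperature-driven relative mosquito
    abundance proxy from trait-based thermal performance curves, and fitting
    a spatial generalized additive model linking bat activity to modeled
    insect prey density. Includes a fully parameterized synthetic landscape
    generator with known ground truth so the whole pipeline can be exercised
    and validated without any external data download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    mgcv,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'grid-utils.R'
    'association.R'
    'batscape-package.R'
    'io.R'
    'landcover.R'
    'mosquito.R'
    'roost.R'
    'presence.R'
    'synthetic.R'
    'pipeline.R'
    'plots.R'
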