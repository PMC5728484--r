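Package: habscape
Title: Township-Scale Landcover Simulation, Habitat Suitability Surfaces,
    and Conservation Cost Accounting
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates township-scale categorical landcover rasters from a
    stated landcover composition, derives multi-scale circular moving-window
    landcover proportions, evaluates a log-linear species-habitat model to
    predict a relative habitat-suitability surface, and computes the 10-year
    economic cost of converting a baseline landscape into a user-specified
    management scenario (Conservation Reserve Program incentives, tree
    removal, wetland restoration). Designed as a scriptable decision-support
    engine for upland gamebird habitat management.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'composition.R'
    'economics.R'
    'utils.R'
    'landscape.R'
    'focal.R'
    'io-raster.R'
    'suitability.R'
    'profiles.R'
    'pipeline.R'
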