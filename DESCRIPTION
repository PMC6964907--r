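Package: paleoniche
Title: Seasonal Climatic Niche Models and Residency Classification at
    Paleontological Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits presence-background maximum-entropy climatic niche models
    from seasonal occurrence records, projects them onto Last Glacial Maximum
    climate raster stacks, converts suitability to presence/absence with a
    percentile training-presence threshold, and measures the distance from a
    focal fossil site to the nearest predicted cell. Per-species seasonal
    distances are classified into residency statuses at each epoch, and
    summarised as shift cross-tabulations, Simpson species turnover, and
    Levins inverse-concentration niche breadths. A synthetic-data generator
    produces two-epoch climate surfaces and species with known niches and
    known residency statuses so that every stage of the pipeline can be
    validated against ground truth at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    geosphere,
    grDevices,
    jsonlite,
    mgcv,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
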