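Package: fcbs
Title: Forest Carbon Budget Scenarios for Bark-Beetle Calamity Projections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An age-cohort, yield-curve-driven forest carbon budget simulator
    with the 21-pool CBM-CFS3 pool structure, proportional disturbance
    transfer matrices, and four management/disturbance scenario engines
    (Green, Red, Black, Black rep.) for projecting carbon stock development
    of a spruce-dominated forest estate through a bark-beetle calamity.
    Includes dead-organic-matter spinup, sanitary-priority harvest
    allocation with deficit tracking, snag-backlog handling, species-change
    replanting, IPCC-pool reporting, LULUCF accounting arithmetic, and a
    seeded synthetic national dataset generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
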