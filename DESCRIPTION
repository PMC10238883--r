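Package: plasticfate
Title: Multimedia Mass-Balance Modelling of Nano- and Microplastic Fate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multimedia 'unit world' model for the environmental fate of
    nano- and microplastic particles.  Compartments (air, fresh and marine
    water, sediments and soils) across nested regional, continental and
    global scales are linked by first-order process rate constants:
    Stokes settling with buoyancy handling, Smoluchowski heteroaggregation
    with natural colloids and coarse suspended particulate matter,
    atmospheric deposition, runoff, erosion, resuspension, burial,
    inter-scale advection, and fragmentation/degradation treated as pure
    removal.  Steady-state and dynamic mass balances are solved by matrix
    algebra and reported as mass and particle-number concentrations split
    over three particulate species (free, colloid-heteroaggregated and
    attached to coarse particles).  A probabilistic layer samples particle
    properties, sector emissions with sewage-treatment routing and removal
    constants, propagates them by Monte Carlo and summarises results as
    percentile ranges and Spearman rank sensitivities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    deSolve,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
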