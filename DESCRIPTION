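Package: foliarflux
Title: Diffusion Modelling of Lipophilic Pesticide Uptake into Plant Cuticles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the uptake of a lipophilic agrochemical from a drying,
    coffee-ring-pinned droplet into a thin plant cuticle as dimensionless
    axisymmetric Fickian diffusion beneath a saturated contact disk with
    zero-flux ("wax reservoir") boundaries elsewhere. Provides a
    backward-implicit finite-volume simulator for the dimensionless uptake
    curve, the four closed-form limiting regimes (Cottrell, Shoup-Szabo,
    Crank plane-sheet and cylinder long-time limits) that bracket it,
    scaling between dimensionless and laboratory units via reference time
    and mass, least-squares inference of the cuticular diffusion
    coefficient and saturation concentration from droplet-array uptake
    assays, deposit-characterisation arithmetic (ring mass partition,
    particle surface density, interparticle spacing, diffusion-zone overlap
    time), and a synthetic assay generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
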