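Package: periflow
Title: Peri-Bracket Salivary Flow Simulation and Orthodontic Plaque Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale computational model of saliva flow over a tooth
    surface carrying an orthodontic bracket, with or without an archwire.
    Builds a parametric vestibular domain with an immersed bracket/wire
    mask, integrates the transient incompressible Navier-Stokes equations
    under a sinusoidal swallow inflow using a staggered-grid projection
    method, and quantifies the peri-bracket flow field: regional average
    near-wall velocity, low-velocity area and vortex area in the four 2-mm
    regions around the bracket base. A companion biostatistics arm
    estimates bacterial loads from serial-dilution plating (log10 CFU),
    summarises per-site microbial counts and longitudinal periodontal
    indices (gingival index, pocket depth), and runs the paired tests used
    in orthodontic plaque studies. Seeded synthetic cohort and analytic
    flow-field generators make every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
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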