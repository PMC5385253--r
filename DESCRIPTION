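Package: crowdpore
Title: Langevin Dynamics of Driven Polymer Translocation Through a Crowded Channel
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained Langevin-dynamics simulator for the electrically
    driven translocation of a bead-spring polymer through a cylindrical
    channel crowded with static spherical obstacles. The chain is a
    FENE-bonded, WCA-repulsive (Kremer-Grest) polymer; the channel is lined
    with stationary wall particles and the membrane is a repulsive particle
    lattice, so the only path from the cis to the trans side is through the
    pore. Provides first-passage event bookkeeping (translocation time,
    per-bead channel entry and exit times, success/failure statistics),
    ensemble drivers with deterministic per-run seeding, and observables:
    translocation probability with Wilson intervals, per-segment
    translocation-time profiles, gyration-tensor shape factor profiles,
    beads-in-channel profiles, and weighted power-law fits of translocation
    time against driving force.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
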