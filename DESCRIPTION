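Package: poremd
Title: Coarse-Grained Langevin Dynamics of Polymer Translocation Through
    Nanopores in Vibrating Membranes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulator and analysis toolkit for forced translocation of a
    structured bead-spring polymer (a minimal single-stranded DNA model) through
    a nanopore carved in a graphene-like honeycomb membrane. The membrane can be
    immobile or kinetic, with beads tethered to their lattice anchors by
    harmonic springs and coupled to their own Langevin thermostat, so that pore
    deformability and thermal vibrations can be switched on independently of the
    polymer thermostat. Includes the WCA/FENE force field, a BAOAB Langevin
    integrator with per-group temperatures, the full translocation protocol
    (pinned-bead thermalization, force switch-on, first-passage detection,
    failed-slide rejection), ensemble drivers, and analysis of translocation
    times: means and errors, inverse-Gaussian first-passage fits, power-law
    force scaling, normalized ratios against reference membranes, and free-chain
    validation observables (gyration radius, center-of-mass diffusion).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    yaml,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
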