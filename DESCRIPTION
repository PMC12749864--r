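Package: poreflux
Title: Ion Channel Permeation Analysis with a Brownian Channel Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Trajectory analysis toolkit for ion permeation through membrane
    channel pores, built around a reduced Brownian (overdamped Langevin)
    simulator of ions moving along a channel axis through a parameterized
    free-energy landscape with binding wells, a gate barrier, a transmembrane
    field and screened ion-ion repulsion.  Provides permeation-event
    detection and single-channel conductance estimation, HOLE-style
    inscribed-sphere pore-radius profiling, time-averaged 3D ion-density
    grids with threshold-based binding-site segmentation, coordination-number
    counting, RMSD utilities, umbrella-sampling window generation and a
    weighted histogram analysis method (WHAM) estimator of the potential of
    mean force with overlap diagnostics and barrier-height extraction,
    including multi-ion (knock-off) configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    bio3d,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
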