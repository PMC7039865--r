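Package: ionpath
Title: Ion Permeation Pathway Analysis for Membrane Channel Trajectories
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and characterises ion-conduction pathways in molecular
    dynamics trajectories of membrane channels.  Provides a two-stage
    open-conformation screen (maximal-inscribed-sphere pore profiling along
    the membrane normal, followed by a grid-based tunnel search with
    throughput-cost scoring), lining-residue statistics and Ward clustering
    of open-channel conformations, ion-protein contact maps and per-ion
    membrane-crossing tracks, dynamical-network analysis of correlated
    residue motions with exact suboptimal-path enumeration, and a
    self-contained well-tempered metadynamics engine (distance collective
    variable, wall and angle restraints, overdamped Langevin dynamics,
    free-energy reconstruction and 2D projection).  A synthetic-trajectory
    generator with analytic ground truth makes every stage testable without
    molecular dynamics output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
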