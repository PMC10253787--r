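Package: gatescan
Title: Trajectory Analysis of Redox-Gated Tetrameric Ion Channels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for molecular dynamics trajectories of
    tetrameric ion channels such as TRPV1, focused on comparing two
    conformational or redox states. Provides least-squares superposition
    with per-residue RMSF and fractional fluctuation differences,
    HOLE-style pore radius profiling with water-permeability
    classification and permeation-event counting, radius-of-gyration
    series, S6-style helix twist angles, per-subunit Calpha
    distance-difference and correlation maps, geometric hydrogen-bond
    occupancy with differential analysis between states, and dihedral
    principal component analysis with free-energy surfaces. A synthetic
    tetrameric-channel generator with known ground truth (gate aperture,
    per-residue fluctuation amplitudes, planted hydrogen bonds,
    traversing waters) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
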