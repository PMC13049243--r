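Package: rosettecmrf
Title: Rosette Cardiac MR Fingerprinting with Multi-Echo Deep Image Prior Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and reconstruction toolchain for rosette-trajectory cardiac
    magnetic resonance fingerprinting (cMRF). Designs multi-echo rosette k-space
    readouts, simulates transient-state fingerprints with an extended phase graph
    (EPG) engine including inversion and T2-preparation, compresses dictionaries to
    a low-rank temporal subspace, and reconstructs subspace-echo images from
    non-Cartesian multi-coil k-space by direct gridding, locally-low-rank plus
    total-variation regularized iteration, or a per-scan deep-image-prior network
    optimized through the full encoding model with static off-resonance correction.
    Reconstructed images are converted into water/fat-separated T1, T2, T2*,
    spin-density and proton-density fat-fraction maps via dual-exponential T2*
    fitting, IDEAL chemical-shift separation and dictionary pattern matching.
    Includes digital cardiac and vial phantoms and a full acquisition simulator
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
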