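Package: cusi
Title: Coded-Wavefield Computational Ultrasound Imaging and 4D Doppler
    Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and model-based reconstruction for computational
    ultrasound imaging (cUSi) with an undersampled matrix probe and a
    phase-screen encoding mask. Provides angular-spectrum wavefield
    propagation, synthetic per-element calibration fields, Hadamard
    synthetic-aperture transmit encoding, frequency-domain acquisition
    simulation of point-scatterer and flow phantoms, preprocessing
    (jitter rejection, block-prefix dropping, SVD clutter filtering),
    a matrix-free forward/adjoint imaging operator with phase-only
    matched-filter, LSMR and TwIST solvers, power and color Doppler
    formation including a subframe running-average scheme, and
    system-matrix resolution, side-lobe, k-space and SNR metrics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
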