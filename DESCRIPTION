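Package: anlcsim
Title: Interferometric Phase-Imaging Simulation for Nanoliter Container Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scalar-wave simulation of an interference microscope imaging a
    sperm-cell refractive-index phantom inside addressable nanoliter
    containers (ANLCs). Builds voxelized 3D phantoms for four micro-well
    designs (pyramid, truncated pyramid, flat-bottom cylinder,
    concave-bottom cylinder), propagates a Gaussian illumination beam
    through them by the band-limited angular-spectrum / multislice method,
    synthesizes phase-shifted and off-axis interferograms, retrieves and
    unwraps the specimen phase, and quantifies design-dependent retrieval
    artifacts (halo strength, RMS phase error, cross-section fidelity).
    Also includes an ordinary-differential-equation model of solute
    concentration in a nanoliter aqueous droplet losing water into a
    covering oil layer, and the water-saturated-oil remedy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    EBImage,
    pracma,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
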