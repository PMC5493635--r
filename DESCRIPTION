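Package: blinkcomp
Title: Eigen-Analysis of Image Stacks of Blinking Fluorophores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes the frame-correlation matrix of a fluorescence image
    stack of independently blinking emitters into spatial component matrices
    (the rank-one mean-image component and the cross-pixel auto- and
    cross-emitter second-moment components) weighted by photon-statistics
    coefficients, and quantifies how each component supports resolution
    beyond the diffraction limit. Includes a 1-D Airy/Gaussian optical model
    and emitter-to-pixel system matrix, a truncated power-law on/off blinking
    and photon-count simulator, Poisson-noise injection at a prescribed peak
    signal-to-noise ratio, resolution diagnostics (full width at half
    maximum, minima-to-maxima ratio, magnitude-versus-separation curves and
    their inflection points), a single-window MUSIC pseudo-spectrum engine
    operating on individual component matrices, and second-order
    super-resolution optical fluctuation imaging (SOFI) with time lag.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
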