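Package: dyncdi
Title: Dynamic Coherent Diffractive Imaging with Spatio-Temporal and
    Probe Constraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Iterative phase retrieval for time-resolved lensless X-ray
    imaging of dynamic samples illuminated by a defocused Fresnel zone
    plate probe. Reconstructs a sequence of complex sample transmission
    functions and the unknown probe from per-frame far-field diffraction
    intensities by wrapping ePIE-style updates with three additional
    constraints: transfer of a time-invariant static region between
    frames, transfer of low spatial frequencies between adjacent frames
    during the early iterations, and a modulus-enforced probe (MEP)
    constraint from a probe-only diffraction pattern, which also drives a
    hybrid input-output probe pre-reconstruction. Includes a physical
    optics simulator (zone-plate probe synthesis, angular-spectrum and
    far-field propagation, Poisson counting noise) that generates
    synthetic dynamic diffraction datasets, Fourier ring correlation
    resolution estimation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    withr,
    yaml,
    tiff,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
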