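Package: fretq
Title: Quantitative Sensitized-Emission FRET Imaging from Three-Image Triplets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibration and analysis of quantitative sensitized-emission FRET
    microscopy from triplets of epifluorescence images (donor-excited donor
    emission, donor-excited acceptor emission, acceptor-excited acceptor
    emission). Spectral crosstalk factors (donor bleedthrough, acceptor direct
    excitation) are measured from single-fluorophore samples, and the emission
    and excitation correction factors are determined in a single step by
    fitting a plane to the pixel cloud in the three-dimensional intensity
    space, assuming a known donor:acceptor stoichiometry. The package computes
    absolute, instrument-independent pixelwise FRET-efficiency and
    stoichiometry maps, E-S histograms, a stoichiometry-based confidence index
    with a weighted Gaussian spatial filter, mixture trajectories for free
    donor or acceptor contamination, and re-implementations of two alternative
    calibration schemes for benchmarking. A forward-model simulator renders
    synthetic image triplets with a configurable camera model so that every
    stage can be validated without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
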