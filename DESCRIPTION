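Package: edsigma
Title: Error Models for Reflection Intensity Uncertainties in 3D Electron Diffraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibration of estimated standard uncertainties (e.s.u.'s) of
    integrated reflection intensities from 3D electron diffraction data.
    Implements four error models: unadjusted counting statistics, sample
    standard deviations of symmetry-equivalent measurements with a binned
    lookup table for singly measured reflections, and two three-parameter
    corrections (SDFAC/SDB/SDADD) calibrated by linearising the normal
    probability plot of normalized deviations against either the mean or the
    maximum of the symmetry-equivalent intensities. Includes iterative Tukey
    fence outlier rejection, symmetry-equivalence grouping for the eleven
    Laue classes, SHELX-style hkl file input and output, peak-integration
    variance propagation for pixelated detectors, merging statistics
    (R_int, R factors, goodness of fit), and a synthetic-data generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
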