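Package: fovsum
Title: Foveal Spatial Summation Analysis with a Computational Observer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating Ricco's area of complete spatial summation
    in the human fovea from adaptive-optics psychophysics, and for comparing
    the measurements against a computational-observer model of the early
    visual system.  Includes maximum-likelihood psychometric fitting with a
    QUEST-style adaptive staircase, two-segment (broken-stick) regression of
    threshold energy versus stimulus area with stratified bootstrap
    confidence intervals, Fourier-optics point-spread functions (diffraction
    limited or from Zernike coefficients), a hexagonal cone mosaic with
    Poisson photoisomerization sampling, a linear-SVM two-interval decoder
    with Gaussian postreceptoral pooling, kernel interpolation between
    bracketing model summation curves, delivery-trace filtering and
    stimulus-travel statistics, subpixel DFT image registration for
    transverse chromatic aberration, and synthetic-data generators with
    known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
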