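Package: scalemorph
Title: Landmark- and Outline-Based Geometric Morphometrics of Fish Scales
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated toolkit for the two geometric-morphometric analyses
    commonly applied to teleost elasmoid scales: a landmark-plus-semilandmark
    Procrustes pipeline (5 fixed landmarks and 80 equidistant semilandmarks
    along the scale margins, generalized Procrustes superimposition with
    optional bending-energy sliding) and an elliptic-Fourier outline pipeline
    (sub-pixel silhouette tracing, equidistant resampling, harmonic-power
    calibration). Both feed a shared ordination and inference layer: principal
    component analysis with shape-vector back-projection, one-way PERMANOVA
    with exact or Monte-Carlo permutation p-values, pairwise comparisons with
    multiplicity adjustment, Welch tests on centroid size, and shape-on-size
    allometry regression. A synthetic scale-silhouette generator with
    controllable margin styles, group effects, and noise makes every pipeline
    stage testable without digitized specimens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    stats,
    utils,
    png,
    tiff,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    optparse
Config/testthat/edition: 3
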