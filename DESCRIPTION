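Package: flymotion
Title: Correlation-Type Motion Detector Arrays and Pattern-Dependent
    Response Modulations in Fly Tangential Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the fly visual-motion pathway from panoramic
    luminance images to the membrane potential of wide-field
    motion-sensitive neurons (lobula-plate tangential cells, LPTCs).
    Includes a synthetic generator for horizontally periodic panoramas
    with natural 1/f-like spatial statistics, Gaussian ommatidial
    optics, Naka-Rushton phototransduction, band-pass lamina filtering,
    four variants of the Hassenstein-Reichardt elementary motion
    detector (basic, adaptive, contrast-saturating, input-line gain
    control), nonlinear gain-control dendritic integration over
    arbitrary receptive fields, and analysis tools quantifying
    pattern-dependent response modulations ("pattern noise") as a
    function of receptive-field size and shape.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
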