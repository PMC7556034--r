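Package: crackfrac
Title: Surface-Crack Morphometry, Heavy-Tailed Size Distributions and
    Quality Features of Baked Goods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative toolkit for characterizing surface cracking of
    baked goods from photographs. Segments crack ("cracking area") regions
    with Otsu thresholding and connected-component particle analysis under
    a physical pixel calibration; models crack-size distributions with a
    log-normal body (back-transformed geometric mean and geometric
    standard deviation) and a power-law tail whose onset is selected by
    minimizing the Kolmogorov-Smirnov distance; computes CIEDE2000 and
    CIE76 color differences with perceptibility banding; and extracts
    puncture-test texture features (crust hardness, crust thickness, work
    of deformation) from force-deformation curves. Seeded synthetic
    generators provide ground-truth images, area samples and force curves
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    jpeg,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
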