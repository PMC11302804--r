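Package: dermadose
Title: In-Vivo Film Versus Treatment-Planning-System Skin Dose Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for comparing in-vivo radiochromic film
    measurements of breast skin dose against treatment-planning-system (TPS)
    dose calculations. Provides a synthetic breast-on-cradle phantom generator
    with parametric buildup dose models, skin structure generation on voxel
    grids (thresholding, contact-surface contours, interior skin rinds via
    anisotropic distance transforms), film dose-map processing (rational
    calibration, edge trimming, adaptive and median filtering, rigid 2D
    registration, fraction averaging), developable-surface dose unfolding,
    cumulative dose-volume histograms with Dx% extraction, 2D gamma-index
    analysis, and pooled dose-difference statistics with Gaussian fits and
    t-tests. Report tables summarise median structure dose,
    calculated-minus-measured shifts, and gamma pass rates per breast region.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
LinkingTo: Rcpp
Config/testthat/edition: 3
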