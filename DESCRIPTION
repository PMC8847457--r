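Package: retorg
Title: Intrinsic-Signal Optoretinography of Dark Adaptation from OCT Intensity Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for intrinsic-signal
    optoretinography (ORG) of rodent dark adaptation with optical coherence
    tomography (OCT). Provides a layered-retina phantom generator with known
    ground truth (staircase axial reflectance, Gaussian axial point-spread
    function, multiplicative gamma speckle, retinal curvature, and
    dark-adaptation kinetics), float-TIFF volume and high-speed recording I/O,
    B-scan flattening anchored on the external limiting membrane, representative
    A-line extraction with outer-nuclear-layer intensity normalization,
    sub-pixel hyper-reflective band and boundary segmentation including the
    double cone/rod outer-segment tip peaks, thickness, reflectivity and
    displacement kinetics, spatiotemporal M-scan construction, and
    repeated-measures ANOVA with Bonferroni post-hoc tests and Pearson
    correlation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
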