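Package: leafspec
Title: Coarse-Fine Wavelength Selection and Pigment Mapping from Leaf
    Hyperspectral Images
Version: 0.1.0
Authors@R: person("Leafspec", "Developers", role = c("aut", "cre"),
    email = "maintainers@leafspec.dev")
Description: Chemometric pipeline for simultaneous quantification of leaf
    photosynthetic pigments (chlorophyll a, chlorophyll b, total
    chlorophylls, total carotenoids) from visible-near-infrared
    hyperspectral reflectance. Implements white/dark reflectance
    correction, elliptical region-of-interest spectrum harvesting,
    Savitzky-Golay and standard normal variate preprocessing, SPXY
    calibration/prediction partitioning, partial least squares
    regression with cross-validation, a coarse-fine wavelength selection
    strategy combining competitive adaptive reweighted sampling (CARS)
    with iteratively retained informative variables (IRIV), pixel-wise
    inversion of fitted models onto leaf images with enhanced Lee
    despeckling and pseudo-colour rendering, and a synthetic
    hyperspectral leaf generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
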