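Package: leafbrdf
Title: Leaf Bidirectional Reflectance: Cook-Torrance Fitting, Surface
    Roughness, Trait-Based Prediction and Canopy Photon Tracing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying and predicting leaf optical properties.
    Reduces goniometer-style angular reflectance scans to calibrated
    bidirectional reflectance (relative to a Lambertian whiteboard), fits the
    three Cook-Torrance BRDF parameters (roughness, diffuse reflection
    coefficient, refractive index) per wavelength by bounded least squares or
    an adaptive two-layer grid search, measures leaf surface roughness from
    cross-section micrographs as the ratio of exact to Gaussian-smoothed edge
    length, computes pigment and specific-leaf-weight trait features, predicts
    BRDF parameters from phenotypic traits with a stacking ensemble
    (support-vector, random-forest and gradient-boosting base learners under a
    linear meta-learner), and traces photons through triangle-mesh canopies to
    summarise scattered photosynthetic photon flux density by layer. Seeded
    synthetic-data generators emulate instrument scans, section images, trait
    tables and layered canopies for fully reproducible validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    tools,
    minpack.lm,
    e1071,
    randomForest,
    xgboost,
    EBImage,
    pracma,
    jsonlite,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
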