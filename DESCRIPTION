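Package: illumipath
Title: Optical-Illumination Path Planning for CT-Guided Needle Biopsy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Plans straight (rigid-needle) percutaneous biopsy trajectories
    from a labelled anatomy volume and a puncture target. The body is treated
    as a light box: a virtual point source at the target casts rays outward,
    Beer-Lambert absorbance accumulates puncture risk along each ray, opaque
    organs block rays outright, and a Lambertian term scores the skin
    insertion angle. The resulting spherical illumination map is projected to
    an equal-area sinusoidal RGB image, thresholded into candidate safe
    regions, summarised by a fixed 50-feature vector per region, and an
    imbalance-aware random forest recommends the entry region, which is
    eroded to a single entry pixel and mapped back to a 3-D skin entry point.
    Includes a seeded synthetic thorax phantom generator so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    yaml,
    jsonlite,
    ranger,
    pROC,
    stats,
    grDevices,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xgboost,
    png,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
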