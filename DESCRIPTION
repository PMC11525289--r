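Package: twpscan
Title: Detection, Sizing and Quantification of Tire Wear Particles in Filter Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An optical-microscopy pipeline for counting and sizing black
    tire wear particles (TWP) collected on filters. Covers the full chain
    from raw RGB filter images to sample-level statistics: contrast
    enhancement and exclusion masking, trainable pixel classification
    (random forest) with automatic IsoData thresholding, separation of
    touching particles by a tolerance-controlled distance-transform
    watershed, per-particle morphometry (Feret diameters by rotating
    calipers, circularity), size-accuracy calibration with segmented
    regression and recovery-based selection of the lower size limit, and
    blank-based limits of detection/quantification with concentration
    extrapolation to particles per kg dry soil. A seeded synthetic
    filter-scene generator with exact ground truth (chromatic diffraction
    halos, organic and charcoal distractors) supports calibration and
    validation without physical samples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ranger,
    minpack.lm,
    tiff,
    png,
    yaml,
    jsonlite,
    optparse,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
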