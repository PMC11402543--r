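Package: gtvhisto
Title: Histopathology Validation of Multi-Observer Prostate Tumour Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Validates intraprostatic gross tumour volume (GTV) delineations
    against whole-mount histopathology ground truth. Provides binary STAPLE
    expectation-maximization fusion of multi-observer delineations per image
    type, union-then-STAPLE combination across image types, construction of
    the histopathology reference lesion from per-slice Gleason-graded
    delineations, isotropic CTV margin expansion on anisotropic voxel grids,
    voxel-wise Dice and lesion-coverage metrics, a penalized in-plane
    translation registration experiment with population-calibrated penalty
    weight, cohort-level summary tables, and a synthetic cohort generator for
    desk-scale testing. Reads and writes NIfTI-1 and NRRD mask volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
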