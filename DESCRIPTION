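Package: gkr50
Title: Analytic Prediction of Intermediate Dose Spill for Gamma Knife
    Radiosurgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts the 50%-isodose spill ratio (R50%) of Gamma Knife
    stereotactic radiosurgery plans from target geometry alone.  Implements
    the closed-form R50% predictor built from planning target volume,
    surface area, equivalent-sphere radius and an empirically calibrated
    dose drop-off distance; the piecewise drop-off model for the Gamma
    Knife Icon with boundary-constrained least-squares refitting from
    phantom sphere plans; a contour-stitching mesh engine that computes
    target surface area and volume from DICOM-RT structure-set contours;
    synthetic voxelated-structure and phantom-calibration generators; and
    batch plan-comparison statistics with Tukey box-plot outlier analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
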