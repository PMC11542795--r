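Package: oriqa
Title: Overlap Robustness Index and Junction QA for Multi-Isocenter VMAT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies treatment-plan robustness in the field-junction
    (overlap) regions of multi-isocenter volumetric modulated arc therapy,
    as used in craniospinal irradiation. Reads cumulative dose-volume
    histograms (DVHs) of the adjacent arc sets from plain-text exports and
    computes the Overlap Robustness Index (ORI), the product of a linear
    coefficient measuring how ramp-like each arc set's DVH is and a
    gradient coefficient normalising the junction dose gradient to an
    ideal 9 cm overlap. Includes a parametric longitudinal two-arc
    junction dose model for simulating isocenter shift errors and the
    resulting Inhomogeneity Ratio (IR), power-law calibration of ORI
    tolerance and action limits against IR thresholds, cohort rank
    statistics, and global gamma-index / profile-difference comparison of
    dose distributions for junction dose verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    nortest
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
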