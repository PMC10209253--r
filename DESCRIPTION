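Package: osteoseg
Title: Automated Detection, Delineation and Quantification of Bone
    Metastases in Whole-Body FDG-PET/CT
Version: 0.1.0
Authors@R:
    person("osteoseg", "developers", email = "osteoseg@example.org",
           role = c("aut", "cre"))
Description: A fully automated pipeline for segmenting and quantifying
    osseous metastatic lesions from co-acquired FDG-PET/CT volumes.  PET
    activity is converted to body-weight standardised uptake values (SUV),
    the low-dose CT is resampled onto the PET grid by bicubic
    interpolation, the skeleton is extracted by Hounsfield-unit
    thresholding with edge smoothing and hole filling, and lesions are
    delineated by absolute SUV thresholding within bone followed by
    connected-component labelling and per-lesion quantification (volume,
    SUVmean, SUVmax).  A validation module matches auto-segmented lesions
    to reference contours, computes voxel-wise confusion statistics, Dice
    coefficients and concordance, sweeps the SUV threshold and selects a
    ROC-optimal operating point.  A deterministic digital phantom
    generator produces co-registered CT/PET volumes with known bone
    anatomy, physiologic extra-osseous uptake and planted lesions
    (including DICOM series and RTSTRUCT export) so the whole pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
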