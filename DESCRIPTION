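Package: msifuse
Title: Multimodal Fusion of Imaging Mass Spectrometry and Histopathology
    for Spot-Level Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing unimodal and multimodal classification of
    pathologist-annotated tissue spots that carry both a MALDI imaging mass
    spectrometry (IMS) profile spectrum and a registered H&E microscopy
    patch.  Implements the IMS preprocessing chain (common-axis resampling,
    baseline subtraction, TIC normalization, integer-lag spectral
    realignment, SNR-based peak picking and peak-matrix assembly), a
    pluggable patch-embedding interface with a deterministic texture
    encoder, training-statistics block standardization and weighted feature
    fusion, patient-grouped nested cross-validation around a linear
    support-vector machine, ROC/PR evaluation with the DeLong test for
    correlated AUCs, low-dimensional projection with hyperspectral RGB spot
    maps, and a paired-modality synthetic cohort generator so the full
    melanoma-versus-nevus comparison can be exercised end to end without
    access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    grDevices
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
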