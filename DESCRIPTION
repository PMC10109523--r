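Package: brainseg
Title: Brain MRI Tumor Detection and Segmentation with U-Net and U-Net++
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end brain MRI tumor analysis: tumor presence detection from
    images or hand-crafted texture features (intensity, GLCM, wavelet, entropy,
    local binary patterns, Haralick), and 2D / multimodal tumor segmentation
    with U-Net and nested U-Net (U-Net++) architectures built to exact layer
    tables with auditable parameter counts. Includes the full preprocessing
    chain for PNG/JPEG/DICOM images, CjData-style HDF5 records and
    four-modality NIfTI volumes, flip/brightness/zoom augmentation, Dice and
    hybrid Dice + cross-entropy losses, a seeded CPU training engine, Dice and
    accuracy evaluation, tumor area/ratio/confidence post-processing, and a
    deterministic phantom generator so every pipeline stage is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    jpeg,
    RNifti,
    rhdf5,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
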