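Package: ostvol
Title: Overall Survival Class Prediction for Glioblastoma from Sectional-Plane Volumetric Radiomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Predicts the overall survival class (short, mid, long term) of
    glioblastoma patients from BraTS-style segmented 3D MRI volumes. The brain
    volume is halved by each of the three anatomical sectional planes
    (mid-sagittal, mid-coronal, mid-horizontal) and twelve voxel-count
    volumetric features are extracted per plane (brain, whole tumor, enhancing
    tumor, necrotic core, edema volumes per half plus whole-brain totals),
    optionally fused with age and resection status. A from-scratch
    single-hidden-layer neural network (tanh hidden layer, softmax output,
    cross-entropy loss) classifies survival into three day-bounded classes.
    Includes NIfTI and clinical CSV input handling, Otsu-threshold brain
    extraction, a synthetic BraTS-style cohort generator for end-to-end
    testing, and an evaluation harness with stratified splits, k-fold
    cross-validation, confusion matrices and one-vs-rest ROC/AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    MASS,
    rpart,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
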