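Package: psmarad
Title: Dual-Modality Radiomics Pipeline for Prostate Lesion Grade Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible radiomics analysis pipeline for predicting
    prostate cancer ISUP grade group (1 versus 2+) from [68Ga]Ga-PSMA-11
    PET uptake maps (SUVbw) and MRI apparent-diffusion-coefficient (ADC)
    maps. Implements IBSI-aligned feature extraction (first-order,
    intensity-volume histogram, morphology, and GLCM/GLRLM/GLSZM/GLDZM
    texture families) on 1 mm isotropic resampled volumes with 32-bin
    grey-level quantisation, contour-perturbation feature-stability
    screening by intraclass correlation, topographic pairing of PET and
    MRI lesion contours, and repeated LASSO-penalised logistic
    cross-validation with ROC/AUC bookkeeping. Includes a synthetic
    dual-modality phantom generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    glmnet,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
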