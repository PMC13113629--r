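Package: petmriq
Title: Hybrid PET/MRI Quantification of Invasive Ductal Breast Carcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantification of breast lesions imaged with simultaneous
    PET/MRI: fixed-threshold PET lesion segmentation, DCE-MRI subtraction
    imaging and semi-quantitative time-intensity-curve parameters, ADC map
    computation from two-point diffusion-weighted imaging, and construction
    of hybrid PET/MRI biomarkers (SUV combined with DCE and ADC parameters).
    Includes the univariate statistical battery relating imaging parameters
    to tissue biomarkers (Spearman correlation with Bonferroni correction,
    Mann-Whitney comparisons with Hodges-Lehmann estimates and adjusted
    confidence intervals, ROC analysis with Youden operating points) and a
    calibrated synthetic cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
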