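Package: activeacq
Title: Closed-Loop Active Acquisition Simulation for Multimodal Neuroimaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates closed-loop ("active") neuroimaging acquisition, in
    which each scan is analysed as soon as it is acquired and the result
    chooses the next scan. Three scenarios are implemented and exercised on
    synthetic data: outlier-guided multi-resolution zooming of a structural
    scan's field of view towards a focal lesion, scored against a normative
    sample by a robust median/MAD outlier distance; sequential modality
    acquisition with a decision-tree age-prediction policy that requests one
    modality at a time; and per-individual Bayesian optimisation (Gaussian
    process regression with expected improvement) over a factor-ordered
    modality axis to locate the modality in which an individual is most
    abnormal. Includes generators for brain-like phantoms with focal lesions
    and for multimodal cohorts with one-factor covariance and an age trend.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    rpart,
    e1071,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
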