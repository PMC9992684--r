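Package: regionage
Title: Region-Wise Multimodal Brain-Age Modelling and Brain-Age-Gap Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds per-region brain-age prediction models from parcellated
    multimodal neuroimaging maps (gray-matter intensity, voxel-wise average
    functional connectivity, fractional anisotropy). Implements resampled
    correlation-based voxel feature selection, Gaussian-process regression of
    age on voxel features with five-fold cross-validation, linear bias
    correction of predicted ages, brain-age-gap computation, and region-wise
    group inference (ANCOVA with partial eta-squared, Benjamini-Hochberg false
    discovery rate control, clinical regressions). Includes a synthetic cohort
    generator with known ground truth so the whole pipeline is testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
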