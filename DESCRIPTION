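Package: restpred
Title: Predicting Individual Task Activation Maps from Resting-State
    Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Vertex-wise encoding models that predict individual task-fMRI
    contrast maps on the cortical surface from resting-state functional
    connectivity features. Implements per-vertex ridge regression with
    generalized cross-validation over the regularization path, a battery of
    connectivity feature extractors (parcel-mean semi-dense connectomes,
    Gaussian random projections, group ICA with dual regression, activity
    flow, and principal-component-regression semi-partial connectomes with
    geodesic masking), group-level baselines, predictive R-squared evaluation
    with variance weighting, paired permutation and corrected resampled
    t-tests, learning curves, behavioral coupling analyses, and a synthetic
    grayordinate cohort generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
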