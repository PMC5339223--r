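Package: angerefp
Title: Anger-Related Neurobehavioral Markers from EEG, Heart Rate and
    Attention Bias
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the neurobehavioral response to a
    naturalistic anger induction and its prospective association with
    post-traumatic stress symptoms (PTSS). Implements the fMRI-inspired
    EEG "electrical fingerprint" of amygdala activity (ridge regression
    from delay-embedded EEG band-power features onto an ROI BOLD time
    course, with hierarchical-clustering model selection, a common
    stacked-subjects model, and cross-validated electrode selection),
    voxel-wise inter-subject correlation with group inference, heart-rate
    series construction from R-peak times, continuous affect-rating
    window identification, dot-probe attention-bias scoring with a 2x2
    mixed ANOVA, and hierarchical multiple regression with standardized
    coefficients, tolerance and the two-predictor reconstruction algebra.
    A fully synthetic multimodal cohort generator with a shared latent
    anger-intensity driver makes every stage testable without access to
    raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
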