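Package: fmaue
Title: Estimating Fugl-Meyer Upper-Extremity Sub-Scores from Wearable IMU Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for estimating the four Fugl-Meyer Assessment
    Upper-Extremity (FMA-UE) sub-scores (shoulder/elbow, wrist, hand,
    coordination) from inertial measurement unit (IMU) recordings of seven
    specialized upper-limb motions. Provides an impairment-graded synthetic
    cohort simulator, signal preprocessing (outlier replacement, zero-phase
    Butterworth filtering, resampling, joint-angle computation, signal-level
    augmentation, sliding windows), a 1530-dimensional kinematic feature
    registry including approximate entropy, a mixup-augmented LSTM
    autoencoder-regressor trained with Adam, and leave-one-subject-out
    cross-validation with the full metric suite (R-squared, Pearson r, MAE,
    NMAE, RMSE, NRMSE), reduced-motion-set ablation and permutation-based
    motion contribution maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    jsonlite,
    signal,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
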