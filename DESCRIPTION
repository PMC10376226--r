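Package: hopwave
Title: Wavelet EMG Pattern Analysis of One-Leg Hop Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Time-frequency analysis of surface electromyography (EMG) recorded
    during one-leg hop tests. Conditions raw EMG (power-line notch and 7-700 Hz
    band-pass), computes intensity patterns with a bank of 14 non-linearly scaled
    Gaussian wavelets, detects hop-phase boundary events from ground reaction
    force, ankle velocity and knee flexion, time- and intensity-normalizes the
    patterns, classifies limb and group membership per muscle with
    1-nearest-neighbor leave-one-out cross-validation, and judges classification
    rates against a binomial critical classification rate with Bonferroni
    adjustment. Includes a synthetic hop-cohort generator with known ground
    truth, plus Pearson correlation and stepwise regression tools relating
    clinical and functional outcomes to knee degeneration scores.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
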