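Package: seasonri
Title: Seasonally Adjusted Laboratory Reference Intervals for Disease
    Classification Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits bounded single-harmonic cosinor models to stratified
    laboratory test results, seasonally shifts clinical reference
    intervals, re-encodes abnormality flags for machine-learning
    features, and quantifies the effect of the adjustment on disease
    classification via paired bootstrap with bias-corrected accelerated
    (BCa) intervals and permutation-sampled Shapley attributions.
    Includes a synthetic electronic-health-record generator that
    emulates the admission, laboratory and outcome structure the
    analysis assumes, so the full pipeline is testable without access
    to person-sensitive registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    readr,
    lubridate,
    stats,
    utils,
    jsonlite,
    yaml,
    digest,
    rpart,
    nnet,
    ranger
Suggests:
    testthat (>= 3.0.0),
    pROC,
    boot,
    withr
Config/testthat/edition: 3
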