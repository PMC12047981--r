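Package: morphobench
Title: Benchmarking Outcome-Prediction Submissions in a Feature Morphospace
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates out-of-sample clinical outcome-prediction submissions
    (squared Pearson correlation, mean squared and absolute error, area under
    the ROC curve against clinically validated poor-outcome thresholds), embeds
    each submission's binary input/method feature combination into a discretized
    two-dimensional morphospace with UMAP, localizes regions of high predictive
    performance with permutation-based max-statistic t-maps, and inverts
    significant local maxima back into binarized "optimal recipe" feature
    combinations per outcome domain. Includes a seeded synthetic cohort and
    submission generator emulating a long-term stroke-outcome benchmarking
    study, so the whole pipeline is testable without restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    matrixStats,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    truncnorm,
    utils,
    uwot
Suggests:
    igraph,
    pROC,
    RNifti,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
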