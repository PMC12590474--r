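Package: flytremor
Title: Tremor Detection and Screen Statistics for High-Speed Leg-Tracking Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies leg tremor in walking Drosophila from high-speed-video
    leg-claw trajectories (FLLIT-style tabular tracking output). Detects shake
    events as amplitude-hysteresis turning points on body-centred,
    body-size-normalised traces, groups them into tremor episodes, and computes
    per-fly tremor rates and line-level screen statistics (penetrance with exact
    binomial intervals, detection-probability design maths, nonparametric group
    comparisons with Dunn post-hoc tests). Includes a tripod-gait simulator with
    ground-truth tremor injection for end-to-end validation, and colocalisation
    metrics (nearest-distance spot classification, Manders coefficients) for
    neurotransmitter-identity quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
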