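Package: cdrhythms
Title: Circadian Rhythm Analysis of Telephone Call Detail Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates circadian rhythms of social activity from telephone
    call detail records (CDRs). Provides hourly call-fraction rhythm
    estimation at the ego and aggregate level, a persistence analysis based
    on the square root of the Jensen-Shannon divergence between successive
    observation periods (with an L2 alternative and Kolmogorov-Smirnov
    confirmation under Holm-Sidak correction), synchronization testing
    between outgoing and incoming call rhythms, and an entropy-based
    alter-specificity analysis with a block-shuffle null model. A seeded
    synthetic CDR generator with ground-truth labels supports calibration
    and power checks when real records are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lubridate,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
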