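Package: proxlogr
Title: Simulation and Analysis of Proximity-Logger Encounter Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with data from animal-borne proximity loggers
    (Encounternet-style radio tags). Provides a seeded simulator of tag
    deployments (home-range movement, log-distance radio propagation with
    antenna-orientation effects, tag firmware state machines with memory,
    clock and battery behaviour), a reconciliation pipeline for saved
    encounter logs (gap merging, dyad calling, broken and staggered log
    classification, uptime restriction), RSSI-distance calibration fitting
    and distance-bin discriminability, log-reliability statistics
    (reciprocity, dyadic-probability models, broken-log comparisons), and
    construction of RSSI-thresholded weighted contact networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    lme4,
    lmerTest,
    igraph,
    yaml,
    withr,
    stats,
    utils
Suggests:
    glmnet,
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
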