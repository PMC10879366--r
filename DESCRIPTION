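Package: ordeeg
Title: Causal Ordinal-Entropy Analysis of Anesthesia EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Online-monitoring-compatible ordinal analysis of multichannel
    EEG around loss and return of responsiveness under general anesthesia.
    Implements a strictly causal band-limiting and resampling chain (250 Hz
    to 200 Hz through a 1000 Hz intermediate grid and an order-1000
    linear-phase FIR low-pass, constant 500 ms delay), ordinal-pattern
    encoding (embedding dimension 5, lag 1), sliding-window permutation
    entropy and symbolic transfer entropy between frontal and parietal
    channels at transfer delays of 35-60 ms, and an accuracy-based
    responsiveness classification with patient-level bootstrap confidence
    intervals. Includes a seeded generator of synthetic anesthesia-transition
    cohorts for end-to-end validation, CSV/EDF readers and writers, and
    ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
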