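Package: neograde
Title: Automated Grading of Background EEG Abnormality in Term Neonates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automatically grading the degree of background
    abnormality in hour-long neonatal EEG recordings after
    hypoxic-ischaemic encephalopathy. Short overlapping epochs are
    decomposed, via a smoothed Wigner-Ville time-frequency distribution,
    into amplitude-modulation (AM) and instantaneous-frequency (IF)
    sub-signals; per-epoch summary features of these sub-signals drive a
    pairwise multi-class Fisher linear discriminant over six EEG states,
    whose decisions are merged to four grades and post-processed by
    majority vote. Includes a synthetic neonatal-EEG simulator (coloured
    1/f^alpha noise under grade-specific amplitude envelopes) so every
    stage is testable without clinical data, EDF input/output, Cohen's
    kappa scoring, and leave-one-subject-out cross-validation with nested
    greedy parameter and feature selection.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
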