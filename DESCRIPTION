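Package: blockda
Title: Block-Wise Domain Adaptation for Multichannel fNIRS Workload Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cross-subject cognitive-workload classification from epoched
    functional near-infrared spectroscopy (fNIRS) time series. Implements an
    MLP-Mixer style classifier for multichannel hemodynamic epochs, trained with a
    cross-entropy objective augmented by kernel two-sample discrepancies: a
    contrastive (class-aware) domain discrepancy and a block-wise maximum mean
    discrepancy that treats blocks within one subject's session as separate
    domains. Includes a hierarchical synthetic fNIRS generator with explicit
    subject-, session- and block-level distribution shift, split-scenario and
    Wasserstein shift diagnostics, leave-subject-out evaluation, paired t-tests,
    and a channel-masking importance scan.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    readr,
    rhdf5,
    clue,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
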