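Package: iedreview
Title: Self-Adapting Detection and Iterative Review of Interictal Epileptiform Discharges
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Template-matching detection of interictal epileptiform discharges
    (IEDs) in multichannel scalp EEG, combined with a certainty-ranked,
    feedback-driven review loop. A database of spike-wave template waveforms is
    trained on annotated recordings (per-template linear support vector
    machines, property gates, and lifetime true/false detection counts).
    Detection runs a Fourier-accelerated sliding Pearson correlation over every
    channel in three montages (common reference, longitudinal bipolar,
    Laplacian); supra-threshold matches become nominations, which are merged
    into grouped IED nominations and ranked by a certainty value that combines
    member correlations with template reliabilities. An iterative review
    presents the most certain groups in batches, re-ranks the remainder after
    each batch of reviewer feedback, and folds confirmed/rejected outcomes back
    into the template database for sustained learning. Includes a seeded
    synthetic spike-wave EEG generator, EDF input/output, a simulated-reviewer
    harness, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
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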