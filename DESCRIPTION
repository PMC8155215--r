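Package: deltapsi
Title: Beta-Resampling Differential Alternative Splicing from Junction Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantifies the uncertainty of percent-spliced-in (PSI) estimates
    from inclusion/exclusion junction read counts with a Beta(#inc+1, #exc+1)
    emission model, calls differentially spliced events between two conditions
    from resampled emission differences (condition medians, delta-PSI, and the
    probability that the test condition exceeds the reference), and summarises
    the direction of splicing change per event type (exon skipping, intron
    retention, alternative 5'/3' splice sites) with a continuity-corrected
    one-sample proportion test and Wilson confidence interval.  Ships a
    two-condition junction-count simulator with ground truth for calibration
    and power studies, readers and writers for inclusion/design/result tables,
    ggplot2 visualisations, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
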