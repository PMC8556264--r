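Package: qpcrflow
Title: Automated qPCR Quantification, Replicate Filtering and Differential Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reads thermocycler result exports (QuantStudio-style csv/txt),
    filters technical replicates with a dual outlier rule (CT standard
    deviation cut-off plus a preserve-highly-variable guard), quantifies by
    standard-curve absolute quantification, relative delta-CT / delta-delta-CT,
    or a genomic-stability copy-number model, runs differential statistics
    with FDR-corrected pairwise post-hocs, and emits clean/summary
    spreadsheets, statistics tables and grouped bar charts. Includes a seeded
    synthetic-plate generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    ggplot2,
    stats,
    utils,
    withr,
    car
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
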