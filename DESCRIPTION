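Package: blisshit
Title: Bliss-Independence Synergy Scoring and Hit Calling for Combination Drug Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-throughput combination cytotoxicity
    screens on cancer cell-line panels, built around the Bliss independence
    model. Normalizes 96-well fluorescence readouts to vehicle controls, fits
    Hill dose-response curves and inverts them to pick anchor doses, scores
    every primary-by-secondary drug combination for synergy, calibrates an
    empirical percentile hit threshold, and partitions hits across primary
    drugs. Companion molecular-profiling statistics cover paired
    empirical-Bayes moderated t-tests with Benjamini-Hochberg false discovery
    rate control, exact Wilcoxon rank-sum contrasts, percent-inhibition
    summaries, and correlation-distance average-linkage clustering with
    bootstrap branch support. A synthetic-data module generates plate-level
    screens and feature matrices with known ground truth so every stage of the
    pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
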