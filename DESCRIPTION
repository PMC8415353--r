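Package: instaphen
Title: Digital Phenotyping of Instagram Archives
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for digital phenotyping from Instagram-style
    data-export archives. Parses per-participant archives, extracts image
    colorimetry (RGB/HSV moments, circular hue mean, Hasler-Suesstrunk
    colorfulness), aspect-ratio and face-count features, social-connection
    statistics (follower/following ratios, duration-normalized counts) and
    temporal posting profiles, then compares a clinical and a control group
    with normality-gated Welch t / Mann-Whitney U tests, Cohen's d and Hedges
    g effect sizes, and a robust between-within ANOVA on trimmed means with
    winsorized covariances. Includes a fully deterministic synthetic-cohort
    generator so every pipeline stage is testable without patient data, a
    transparent propensity-score matcher for case-control designs, and a
    command-line interface for end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
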