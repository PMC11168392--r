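Package: inflakinetics
Title: Time-Resolved Kinetics of NLRP3 Inflammasome Readouts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for time-resolved analysis of NLRP3 inflammasome readouts in
    live-cell experiments: ASC-speck quantification in fluorescence frames by
    thresholding, connected-component labeling and particle filtering (area and
    circularity gates); first- and second-difference change and acceleration
    metrics with sliding-window peak detection; technical- and experimental-
    replicate aggregation; LDH percent-cytotoxicity normalization and
    IL-1beta:IL-18 ratio trajectories; temporal-association landmarks between
    readouts; and pairwise comparisons by a pooled-resampling bootstrap suited
    to small sample sizes. Includes a synthetic-study generator (trigger-specific
    speck pulses, sigmoidal cytokine and LDH release, simulated fluorescence
    frames) with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    EBImage,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
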