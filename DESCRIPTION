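Package: startlekit
Title: Fear-Potentiated Startle Analysis for Differential Fear Conditioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for eye-blink startle electromyography (EMG) in
    differential fear conditioning experiments: pseudorandomized
    habituation/acquisition/extinction schedule generation, synthetic
    orbicularis-oculi EMG session and cohort simulation, the offline
    preprocessing chain (65 Hz high-pass, rectification, 40-ms moving
    average, 2 Hz drift removal), threshold-based startle-response
    detection with latency-window validation, intertrial-interval
    proportional scoring, and the group-level statistical layer (2x2
    mixed ANOVA with partial eta squared, paired and pooled independent
    t-tests, Pearson correlation and chi-square, contingency-awareness
    classification).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    broom,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
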