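Package: segspeech
Title: Resting-State Network Segregation and Speech Disfluency Across the Adult Lifespan
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how resting-state functional network
    organization relates to naturalistic speech disfluency in adult aging.
    Computes within-network connectivity, between-network connectivity, and
    network segregation for language, default mode, and multiple demand
    networks from ROI time series; parses a documented CHAT-style transcript
    subset into five disfluency subtype rates; fits the moderated regression
    battery (centered predictors, interaction terms, Cook's-distance
    screening, Benjamini-Hochberg FDR); probes interactions with simple
    slopes and Johnson-Neyman regions; and runs nonparametric bootstrap
    mediation (ACME, ADE, proportion mediated). A calibrated synthetic-cohort
    generator with recorded ground truth supports parameter-recovery testing
    of every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    tibble,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
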