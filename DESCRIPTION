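Package: sblfp
Title: Multi-Region LFP Rhythmicity Analysis for Social Discrimination Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-region local field potential (LFP)
    recordings acquired during binary social-discrimination tasks. Provides a
    session/bout data model with validation and on-disk round-tripping, a
    synthetic multi-region LFP generator with controllable band power,
    pairwise coherence, directed lagged coupling and bout-locked modulation,
    multitaper spectrograms and theta/gamma band-power summaries (session-wide
    and bout-locked), Welch magnitude-squared coherence with normalized
    encounter-versus-baseline change statistics, VAR-based spectral
    pairwise-conditional Granger causality, screening statistics (bias
    thresholds, region over-representation, octant classification), and a
    leave-one-subject-out random-forest context decoder with iterative
    regression imputation and a random-classifier null.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    arrow,
    jsonlite,
    randomForest,
    signal,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
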