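Package: emodfc
Title: Dynamic Functional Connectivity of Temporally Localized Emotional
    Events in EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for phase-locking-value (PLV) network
    analysis of event-locked EEG. Band-limits multichannel recordings
    into six canonical frequency bands, extracts 7-second epochs around
    self-reported emotional events and matched baseline epochs, computes
    sliding-window PLV networks per band and time segment, identifies
    significant connections against baseline with a max-statistic
    permutation test controlling the family-wise error rate, selects the
    most emotion-discriminative band by comparing inter-group
    connectivity distances to a global threshold, quantifies the
    temporal variability of dynamic functional connectivity (tvDFC) per
    event, relates that variability to valence/arousal/dominance rating
    scales with mixed-effects regression, and detects network hubs by
    eigenvector centrality against an Erdos-Renyi null. Includes a
    seeded synthetic-data generator with known ground-truth coupling so
    every stage is testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
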