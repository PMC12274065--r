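Package: thalamostate
Title: State-Dependent Thalamic Firing and Loss-of-Movement Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for single-unit thalamic recordings and
    forced-walking-task behavior under sedation. Detects low-threshold
    bursts in spike trains, computes autocorrelogram burst indices and
    per-brain-state tonic/burst firing metrics, classifies regular- vs
    narrow-spiking units, expresses state firing as wake-referenced
    Z-scores, and scores ethanol-induced loss of movement from
    accelerometer or video motion signals using a windowed mean-by-STD
    activity index. Includes constructors for tonic, burst-like and
    phasic ON-OFF stimulation pulse trains with peristimulus response
    statistics, a seeded synthetic-data generator with attached ground
    truth for end-to-end testing, and group/state statistics
    (rank correlation, Levene variance test, Holm step-down decisions,
    firing-feature embedding).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    car,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
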