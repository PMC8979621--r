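Package: sonophys
Title: Analysis of Ultrasound-Evoked Intracellular Neural Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying intracellular membrane-potential responses of
    neurons to pulsed low-intensity ultrasound and to intracellular current
    injection. Provides acoustic dosimetry (spatial-peak pulse-average and
    temporal-average intensities from root-mean-square pressure and duty cycle),
    stimulus-aligned epoch windowing, subthreshold depolarization statistics
    based on windowed medians, threshold-crossing spike detection with action
    potential morphometry (peak-to-trough amplitude, early-repolarization
    half-prominence duration, latency), success-rate summaries, and the
    regression / Kruskal-Wallis / two-way ANOVA layer used to relate responses
    to stimulation parameters. A seeded synthetic trace generator emulates the
    accumulating, slowly decaying ultrasound-induced depolarization and
    modality-specific spike waveforms so the full pipeline can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
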