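Package: odpipe
Title: Ocular Dominance Plasticity Analysis from Eye-Specific Spike Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for quantifying ocular dominance in
    mouse binocular visual cortex from extracellular spike trains recorded
    under eye-specific grating stimulation. Converts stimulus schedules and
    spike-time tables into per-unit evoked and spontaneous firing rates,
    applies responsiveness and adjacent-electrode duplicate filters, computes
    ocular dominance indices, 7-point ocular dominance classes and per-animal
    contralateral bias indices, classifies units into regular-spiking and
    fast-spiking types from waveform half-width and firing rate, quantifies
    layer-resolved cFos/parvalbumin cell densities from labeled point maps,
    and runs the accompanying statistical comparison suite
    (Kolmogorov-Smirnov, ANOVA with Tukey HSD, Kruskal-Wallis with Dunn post
    hoc, Mann-Whitney, unpaired t-tests). A seedable synthetic-data generator
    emulates the six experimental conditions of a monocular-deprivation
    recovery design so that every stage of the pipeline is testable without
    access to raw recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
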