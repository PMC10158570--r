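Package: freqtagsl
Title: Frequency-Tagged EEG Analysis of Auditory Statistical Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for EEG frequency-tagging
    studies of auditory statistical learning in the artificial-language
    paradigm. Generates syllable streams with controlled transitional
    probabilities (pseudoword language and position-controlled baseline),
    audits their amplitude-envelope modulation spectra, simulates
    multi-channel EEG with phase-locked syllable- and word-rate components
    plus 1/f noise, and implements the full analysis chain: triplet-aligned
    epoching, inter-trial phase coherence (ITPC) spectra, one-tailed paired
    t tests with directional default-prior (JZS) Bayes factors,
    cluster-based electrode permutation, by-block mixed-model regression
    with Helmert contrasts, per-participant label-swap permutation tests,
    and scoring plus permutation inference for the explicit 2AFC and
    implicit target-detection behavioral tasks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
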