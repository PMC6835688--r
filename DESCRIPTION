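Package: ocusearch
Title: Dichoptic Visual Search Stimuli, Synthetic Observers, and
    Reaction-Time Analysis for Ocularity-Contrast Saliency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying exogenous attentional capture by ocularity
    contrast (the relative difference between an item's left-eye and
    right-eye input strengths) in dichoptic visual search.  Provides the
    ocularity algebra and per-eye luminance mappings for decrement and
    increment displays, generators for complete dichoptic search arrays and
    session schedules (bar and letter-search designs with positional jitter,
    disparity, vergence anchors, and interleaved baseline / congruent /
    incongruent singleton conditions), a parameterised saliency-capture
    observer that emits button-press reaction times and fixation-level gaze
    traces, and the matching analysis pipeline: outlier exclusion,
    per-condition summaries, baseline normalisation, first-saccade scoring,
    depth and contrast median splits, and matched-sample t-tests.  All
    results are tibbles designed for piped workflows, with broom-style
    tidiers and ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
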