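Package: erpls
Title: Task-PLS and Peak Analysis of Auditory Evoked Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis of longitudinal auditory evoked potential
    (AEP) studies of P2 plasticity. Provides a synthetic-study generator that
    plants session-dependent P2 enhancement into epoched multichannel EEG, the
    standard preprocessing chain (baseline correction, amplitude-threshold
    artifact rejection, trial averaging, Butterworth band-pass filtering,
    common-average re-referencing), P1-N1-P2 peak and windowed-amplitude
    quantification, mean-centered and non-rotated task partial least squares
    (task-PLS) with permutation significance and bootstrap-ratio stability,
    balanced repeated-measures ANOVA with Greenhouse-Geisser correction and
    Bonferroni post-hocs, and signal-detection d-prime scoring of
    two-alternative forced-choice identification logs. All analysis results
    are returned as tibbles with broom-style tidiers and ggplot2 autoplot
    methods.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    generics,
    ggplot2,
    readr,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
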