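Package: napscape
Title: Infant Nap Polysomnography Microarchitecture and Sensory Reactivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for infant daytime-nap polysomnography with
    auditory stimulation. Detects sleep spindles (three-feature sigma-band
    detector), slow waves and evoked K-complexes; computes slow-wave and
    sigma band power (median-combined Welch), event densities,
    stimulus-locked ON/OFF event likelihoods, sleep macroarchitecture
    summaries, arousal density, and caregiver-reported sensory-reactivity
    composites. Includes event-level detector evaluation (precision, recall,
    F1) with threshold grid search against manual annotations, dependent
    correlation comparison, Winsorization, linear mixed-effects models with
    Satterthwaite inference, a zero-inflated beta stage-proportion model,
    and a synthetic polysomnography generator so the full pipeline is
    testable end to end without clinical recordings.
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
    glmmTMB,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
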