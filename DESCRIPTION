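Package: thermopyle
Title: Temperature-Step Analysis of Pyloric Rhythm Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing spike trains of the crustacean pyloric
    central pattern generator recorded during stepped temperature protocols.
    Extracts bursts, cycles, phases and duty cycles from labelled spike
    times; attaches bath temperature to cycles and fits Q10 temperature
    sensitivity of the rhythm frequency; classifies per-cycle smoothed
    temperature and frequency changes to quantify non-monotonic ("jag")
    transition dynamics; tests phase constancy against temperature with
    normality-gated statistics and Bonferroni control; measures
    hyperpolarization-activated current (Ih) amplitude from voltage-clamp
    traces; and simulates ground-truth-parameterised experiments so every
    stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
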