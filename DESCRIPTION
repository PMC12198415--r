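Package: somipipe
Title: Reward-Coding Analysis of Dentate Gyrus Interneuron Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for head-fixed goal-oriented-learning
    electrophysiology sessions: behavioral segmentation and expert/non-expert
    classification, spike-waveform and burstiness unit typing, optogenetic
    tagging of somatostatin interneurons (SOMIs), cross-correlogram detection
    of monosynaptic connections with a partially hollow Gaussian baseline,
    reward-aligned response characterization, a permutation-tested linear
    encoding model, and a Poisson maximum-likelihood reward-anticipation
    decoder. Includes a synthetic-session generator with full ground truth so
    every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
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
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
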