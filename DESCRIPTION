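Package: ccvreading
Title: Articulatory Effort and Eye Movements in the Reading of CCV Trigrams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline linking silent-reading eye fixations on
    consonant-consonant-vowel (CCV) trigrams to speech-motor variables. It
    implements a biophysical vocal-tract area-function model with an
    articulatory effort functional, spectro-temporal landmark extraction of
    phonatory timing variables from audio, standard reading measures (first
    fixation duration, first-pass reading time, total fixation time) from
    fixation-event tables, lip-accelerometer envelope analysis, the study's
    quality-control cascade, and the regression/t-test/ANOVA battery. A
    calibrated synthetic-experiment generator emulates the full design so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    rlang,
    signal,
    pracma,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    readr,
    ggplot2
Config/testthat/edition: 3
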