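Package: rsamarkov
Title: Markov-Chain Analysis of RR-Interval State Transitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying respiratory sinus arrhythmia and heart rate
    variability through a discrete-time Markov chain on inter-beat (RR)
    intervals. Each RR interval is classified as Normal or Arrhythmic against
    a configurable reference duration band, a moving window is slid over the
    resulting state sequence, a row-stochastic 2x2 transition matrix is
    estimated per window by adjacent-pair counting, and window-level
    transition probabilities are pooled per subject group and compared
    between groups with a two-sided Mann-Whitney U test. Includes readers
    and writers for plain-text RR/IBI and single-channel EKG files, an
    automatic R-peak detector, and seed-parameterised synthetic generators
    (hidden two-state RR process, sinusoidally modulated RR series, EKG
    pulse trains) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
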