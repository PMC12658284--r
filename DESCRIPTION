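Package: ictalsync
Title: Ictal-Phase EEG Synchrony from Low-Frequency Imaginary Coherence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies brain synchronization across the phases of cyclic
    electrographic seizures recorded with a reduced scalp EEG montage.
    Computes Welch cross-spectra and low-frequency (1-8 Hz) imaginary
    coherence between all electrode pairs over 10-s windows anchored at
    seizure onset and termination markers, adjusts connectivity matrices
    against the inter-ictal baseline, reduces them to regional averages and
    per-electrode totals, and tests for terminal hypersynchronization with
    REML linear mixed-effects models, Type II Wald chi-square tests and
    Dunnett contrasts against the termination phase. Includes a synthetic
    cyclic-seizure cohort generator (lagged coupling, volume-conduction
    mixing, programmable terminal coupling boost) with ground truth for
    calibration of the whole pipeline, and minimal EDF input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    car,
    emmeans,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
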