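Package: somnarch
Title: Rodent EEG/EMG Sleep Scoring, Architecture Metrics, and Trauma Cohort Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automatic vigilance-state scoring of mouse EEG/EMG recordings
    from spectral band-power thresholds (WAKE/NREMS/REMS plus microarousal
    relabeling), quantification of sleep architecture per Zeitgeber phase
    (occupancy, episodes, transitions, state-specific band-power AUC, baseline
    normalization), behavioral endpoints for fear-conditioning studies
    (acoustic startle amplitudes, freezing fractions), and the group/day
    repeated-measures and correlation statistics used to link pre-trauma REMS
    continuity to post-trauma hyperarousal. Includes a calibrated synthetic
    generator for hypnograms, state-conditional EEG/EMG signals, and trauma
    cohorts so the full pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
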