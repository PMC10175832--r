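Package: eegconn
Title: Band Power, Cross-Frequency Coupling and Directed Connectivity for Terminal EEG/ECG Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for multichannel scalp EEG with a simultaneous ECG
    channel, aimed at characterizing large-scale brain dynamics across clinically
    defined stages (e.g. before and after withdrawal of life support). Provides
    EDF/EDF+ ingestion with a minimal writer, average re-referencing, zero-phase
    notch filtering, short-time Fourier band power and fold-change maps,
    modulation-index phase-amplitude coupling (comodulograms, local and
    cross-regional electrode matrices, circular-shift surrogate thresholds),
    Welch magnitude-squared coherence with temporo-parieto-occipital summaries,
    normalized symbolic transfer entropy for directed connectivity with
    feedforward/feedback summaries, ECG R-peak detection, heart-rate-variability
    metrics, asystole detection and electrocardiomatrix images, plus a seeded
    synthetic-session generator with known ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
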