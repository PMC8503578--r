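Package: seizcoh
Title: Scalp-EEG Seizure-Onset Extraction Validated Against Intracerebral Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative pipeline for extracting seizure-onset activity from
    scalp EEG with extended-infomax independent component analysis and
    validating it against simultaneous stereo-EEG (SEEG) recordings. Provides
    a synthetic simultaneous scalp/SEEG session generator with a dipolar
    ictal source in a spherical head model, dual-clock stream alignment from
    digital triggers and a 50 Hz reference sine, Hamming windowed-sinc
    band-pass filtering and bipolar re-referencing, equivalent current dipole
    fitting with goodness of fit, Morlet wavelet coherence with
    surrogate-noise significance thresholds and the significant normalized
    area (SNA) statistic, and dipole-to-seizure-onset-zone spatial analysis.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
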