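Package: megevoke
Title: Evoked-Response MEG/EEG Analysis from Raw Recordings to Group Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for event-related MEG/EEG analysis: trigger decoding from
    bit-coded stimulus channels, artifact detection (blinks, heartbeats, cHPI
    transients, movement and muscle segments), zero-phase spectral filtering with
    explicit transient accounting, signal-space projection, epoching and weighted
    trial averaging, spherical-head forward models (Sarvas magnetometer fields,
    concentric three-shell EEG potentials), depth-weighted minimum-norm source
    estimation with dSPM and sLORETA standardization, Morlet wavelet
    time-frequency maps with edge masking and ERS/ERD scaling, and group-level
    nonparametric inference (sign-flip permutation t-tests, FDR, cluster-based
    correction). Includes a synthetic multi-subject simulator with full ground
    truth, a scriptable pipeline runner with execution reports, and readers and
    writers for BIDS-style channels.tsv and events.tsv sidecars.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
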