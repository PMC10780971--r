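Package: bedpress
Title: Blood-Pressure Waveform Reconstruction from Bed Load-Cell Ballistocardiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs a continuous arterial blood-pressure (BP) waveform
    from the four load-cell (ballistocardiography) signals recorded under the
    legs of a bed, using a sliding-window stacked-LSTM regressor, and derives
    systolic and diastolic blood pressure from the reconstructed waveform by
    derivative zero-crossing extrema detection with amplitude gates and
    refractory separation. Includes zero-phase band-pass conditioning and
    decimation of the raw signals, participant-disjoint dataset partitioning,
    Bland-Altman agreement analysis at the five-second-window and recording
    level, and a synthetic cohort simulator that generates paired load-cell /
    BP recordings so the full pipeline can be trained and evaluated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
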