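Package: ecgbeat
Title: Real-Time ECG Heartbeat Classification with Recurrent and Convolutional Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end toolkit for AAMI five-class heartbeat classification
    from single-lead ECG. Provides a synthetic ECG generator with known ground
    truth, readers and writers for WFDB-format records and annotations, the
    standard conditioning chain (Fourier resampling, VisuShrink wavelet
    denoising, double-median-filter baseline removal, z-score normalisation),
    Pan-Tompkins QRS detection with local R-peak refinement, three per-beat
    feature representations (RR-interval statistics over a 42-beat rolling
    window, morphology segments, discrete-wavelet approximation coefficients),
    three trainable network architectures (LSTM, bidirectional LSTM, LSTM-FCN)
    with closed-form parameter accounting, and a streaming-inference simulator
    with per-beat latency reporting against the 0.6 s real-time bound.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    callr,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
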