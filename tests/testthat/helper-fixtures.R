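# Shared fixtures and independent oracles. Everything is generated in code;
# slow objects are cached for the duration of the test run.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# A clean synthetic record used across detector/feature tests.
clean_record <- function() {
  cached("clean_record", synth_record(synth_config(
    duration = 120, fs = 360, rr_mean = 0.75, rr_jitter_sd = 0.03,
    hf_noise_sd = 0, baseline_amplitude = 0, seed = 7)))
}

# A small trained wavelet-feature classifier for streaming tests: trained on
# one synthetic record with a class mix rich enough to cover all classes.
tiny_wavelet_model <- function() {
  cached("tiny_wavelet_model", {
    rec <- synth_record(synth_config(
      duration = 400, fs = 360, rr_mean = 0.7, rr_jitter_sd = 0.04,
      class_mix = c(N = 0.3, S = 0.2, V = 0.2, F = 0.15, Q = 0.15),
      hf_noise_sd = 0.02, baseline_amplitude = 0.1, seed = 11))
    pp <- preprocess_signal(rec$signal, rec$fs)
    peaks <- correct_rpeaks(pp$signal, rpeak_set(rec$rpeaks, rec$fs))
    seg <- segment_beats(pp$signal, peaks$sample, rec$labels)
    wf <- wavelet_features(seg, length_out = 100)
    fit_beat_classifier(wf, lstm_fcn_spec(100, 8),
                        train_config(epochs = 30, batch_size = 32, seed = 3))
  })
}

# Brute-force sliding median with reflect padding: the independent oracle
# for the median-filter implementation.
brute_force_median <- function(x, m) {
  n <- length(x)
  pad <- (m - 1) %/% 2
  xp <- c(x[(pad + 1):2], x, x[(n - 1):(n - pad)])
  vapply(seq_len(n), function(i) median(xp[i:(i + m - 1)]), numeric(1))
}

# Independent per-beat RR-feature builder: naive loops, no shared code with
# rri_features() beyond the definition of the features themselves.
brute_force_rri <- function(peaks, labels, fs, window = 42L) {
  n <- length(peaks)
  rows <- list()
  for (i in seq_len(n)) {
    if (i < 3 || i > n - 1 || i < window + 2) next
    rr0 <- (peaks[i] - peaks[i - 1]) / fs
    rr_prev <- (peaks[i - 1] - peaks[i - 2]) / fs
    rr_next <- (peaks[i + 1] - peaks[i]) / fs
    hist <- numeric(window)
    for (k in seq_len(window)) {
      j <- i - 1 - k   # the k-th interval before the current one ends at peak i - k
      hist[k] <- (peaks[j + 1] - peaks[j]) / fs
    }
    avg <- mean(hist)
    sdv <- sqrt(mean((hist - avg)^2))
    rows[[length(rows) + 1]] <- data.frame(
      beat = i,
      rr0 = rr0, rr_prev = rr_prev, rr_next = rr_next,
      rr0_over_avg = rr0 / avg,
      t_rr0 = if (sdv > 0) (rr0 - avg) / sdv else 0,
      rr_prev_over_avg = rr_prev / avg, rr_prev_over_rr0 = rr_prev / rr0,
      rr_next_over_avg = rr_next / avg, rr_next_over_rr0 = rr_next / rr0)
  }
  do.call(rbind, rows)
}

stream_record_through <- function(model, record, chunk_s) {
  sess <- stream_session(model, fs_source = record$fs)
  step <- max(1L, as.integer(round(record$fs * chunk_s)))
  n <- length(record$signal)
  for (start in seq(1, n, by = step)) {
    idx <- start:min(start + step - 1L, n)
    ingest(sess, stream_chunk(0, record$fs, record$signal[idx]))
  }
  sess
}
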