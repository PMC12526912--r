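# Signal conditioning chain applied before feature extraction, in fixed
# order: resample to the training rate, wavelet denoising, baseline-wander
# removal, z-score normalisation.

#' Preprocessing configuration
#'
#' Parameters of the conditioning chain. Defaults reproduce the deployed
#' pipeline: resampling to 360 Hz, VisuShrink soft-threshold denoising with a
#' db8 wavelet at 10 decomposition levels, and a 71-then-215-sample double
#' median filter for baseline-wander estimation (windows in samples at
#' 360 Hz; both must be odd).
#'
#' @param fs_target Target sampling rate in Hz.
#' @param denoise_wavelet Wavelet used for denoising.
#' @param denoise_levels Requested decomposition depth; clamped (with a
#'   warning) to the maximum feasible depth for short signals.
#' @param bw_window_1,bw_window_2 Median-filter window lengths in samples.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(fs_target = 360, denoise_wavelet = "db8",
                              denoise_levels = 10L,
                              bw_window_1 = 71L, bw_window_2 = 215L) {
  check_scalar(fs_target, "fs_target")
  check_scalar(denoise_levels, "denoise_levels")
  for (w in c(bw_window_1, bw_window_2)) {
    if (w < 3 || w %% 2 == 0) {
      stop_ecg("Median-filter windows must be odd and >= 3.",
               class = "ecgbeat_validation_error")
    }
  }
  structure(list(fs_target = fs_target, denoise_wavelet = denoise_wavelet,
                 denoise_levels = as.integer(denoise_levels),
                 bw_window_1 = as.integer(bw_window_1),
                 bw_window_2 = as.integer(bw_window_2)),
            class = "preprocess_config")
}

#' Band-limited (Fourier) resampling
#'
#' Resamples a uniformly sampled signal to a new rate through the frequency
#' domain: the spectrum is truncated (downsampling) or zero-padded
#' (upsampling), with the Nyquist bin split or folded so that real signals
#' stay real. The output length is `round(length(x) * fs_out / fs_in)`.
#'
#' @param x Numeric signal (finite, length >= 2).
#' @param fs_in,fs_out Input and output sampling rates in Hz.
#' @return Numeric vector of the resampled signal.
#' @export
resample_signal <- function(x, fs_in, fs_out) {
  check_numeric_signal(x)
  check_scalar(fs_in, "fs_in"); check_scalar(fs_out, "fs_out")
  n <- length(x)
  if (n < 2) stop_ecg("Need at least 2 samples.", class = "ecgbeat_validation_error")
  m <- as.integer(round(n * fs_out / fs_in))
  if (m == n) return(x)
  X <- fft(x)
  Y <- complex(m)
  nmin <- min(n, m)
  half <- nmin %/% 2L
  # positive frequencies 0 .. ceil(nmin/2)-1
  npos <- as.integer(ceiling(nmin / 2))
  Y[seq_len(npos)] <- X[seq_len(npos)]
  # negative frequencies
  nneg <- as.integer(floor((nmin - 1) / 2))
  if (nneg > 0) {
    Y[m - seq_len(nneg) + 1L] <- X[n - seq_len(nneg) + 1L]
  }
  if (nmin %% 2L == 0L) {
    s <- half
    if (m < n) {
      # fold the component that aliases onto the new Nyquist bin
      Y[s + 1L] <- X[s + 1L] + X[n - s + 1L]
    } else {
      Y[s + 1L] <- X[s + 1L] / 2
      Y[m - s + 1L] <- X[s + 1L] / 2
    }
  }
  Re(fft(Y, inverse = TRUE)) / n
}

soft_threshold <- function(x, threshold) {
  sign(x) * pmax(abs(x) - threshold, 0)
}

#' VisuShrink wavelet denoising
#'
#' Removes high-frequency noise by multilevel wavelet decomposition, soft
#' thresholding of every detail band with the universal threshold
#' `sigma * sqrt(2 log N)`, and reconstruction. The noise scale `sigma` is
#' estimated from the finest detail band as `median(|D1|) / 0.6745`.
#'
#' @param x Numeric signal.
#' @param wavelet Wavelet name.
#' @param levels Requested decomposition depth (clamped for short signals).
#' @return Denoised signal, same length as `x`.
#' @export
wavelet_denoise <- function(x, wavelet = "db8", levels = 10L) {
  check_numeric_signal(x)
  maxlev <- dwt_max_level(length(x), wavelet)
  if (maxlev == 0L) return(x)
  if (levels > maxlev) {
    warn(sprintf("Clamping denoising depth from %d to %d for signal length %d.",
                 levels, maxlev, length(x)))
    levels <- maxlev
  }
  dec <- dwt_decompose(x, wavelet, levels)
  d1 <- dec$d[[dec$level]]           # finest detail band
  sigma <- median(abs(d1)) / 0.6745
  threshold <- sigma * sqrt(2 * log(length(x)))
  dec$d <- lapply(dec$d, soft_threshold, threshold = threshold)
  dwt_reconstruct(dec)
}

#' Running median filter
#'
#' Replaces each sample with the median of the surrounding window (reflect
#' padding at the edges, mirroring about the end samples), preserving the
#' signal length.
#'
#' @param x Numeric signal.
#' @param window Odd window length `M`, with `M <= 2 * length(x) - 1`.
#' @return Filtered signal, same length as `x`.
#' @export
median_filter_1d <- function(x, window) {
  check_numeric_signal(x)
  check_scalar(window, "window")
  n <- length(x)
  if (window %% 2 == 0) {
    stop_ecg("`window` must be odd.", class = "ecgbeat_validation_error")
  }
  if (window > 2 * n - 1) {
    stop_ecg("`window` too large for the signal.", class = "ecgbeat_validation_error")
  }
  if (window == 1) return(x)
  pad <- (window - 1L) %/% 2L
  xp <- c(x[(pad + 1L):2L], x, x[(n - 1L):(n - pad)])
  y <- stats::runmed(xp, window, endrule = "keep")
  y[(pad + 1L):(pad + n)]
}

#' Baseline-wander estimation and removal
#'
#' Estimates the slow drift of the isoelectric line with a cascade of two
#' median filters (a short window that suppresses the QRS complexes, then a
#' long window that extracts the respiratory-scale trend) and subtracts it.
#'
#' @param x Numeric signal.
#' @param config A [preprocess_config()].
#' @return A list with `corrected` (signal minus trend) and `trend`; their sum
#'   reproduces the input to floating-point round-off. Trend estimates within
#'   half a window of the record ends lean on reflect padding and are less
#'   accurate there.
#' @export
remove_baseline <- function(x, config = preprocess_config()) {
  check_numeric_signal(x)
  if (length(x) <= config$bw_window_2) {
    stop_ecg("Signal shorter than the largest baseline window.",
             class = "ecgbeat_validation_error")
  }
  trend <- median_filter_1d(median_filter_1d(x, config$bw_window_1),
                            config$bw_window_2)
  list(corrected = x - trend, trend = trend)
}

#' Z-score normalisation
#'
#' Centers and scales to zero mean and unit standard deviation, using the
#' population (1/n) standard deviation.
#'
#' @param x Numeric, non-constant signal.
#' @return Normalised signal.
#' @export
zscore <- function(x) {
  check_numeric_signal(x)
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma == 0) {
    stop_ecg("Cannot z-score a constant signal (sd = 0).",
             class = "ecgbeat_validation_error")
  }
  (x - mu) / sigma
}

#' Full conditioning chain
#'
#' Applies the fixed pipeline resample -> denoise -> baseline removal ->
#' z-score and returns the conditioned signal at the target rate.
#'
#' @param x Numeric signal.
#' @param fs_in Input sampling rate in Hz.
#' @param config A [preprocess_config()].
#' @return A list with `signal` (conditioned), `fs` (target rate), and
#'   `trend` (the removed baseline estimate, at the target rate).
#' @export
preprocess_signal <- function(x, fs_in, config = preprocess_config()) {
  y <- resample_signal(x, fs_in, config$fs_target)
  y <- wavelet_denoise(y, config$denoise_wavelet, config$denoise_levels)
  bw <- remove_baseline(y, config)
  list(signal = zscore(bw$corrected), fs = config$fs_target, trend = bw$trend)
}
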