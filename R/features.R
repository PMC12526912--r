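# Per-beat feature representations: RR-interval statistics over a rolling
# window, morphology segments around corrected R peaks, and DWT
# approximation-coefficient features, each with retention accounting.

new_beat_features <- function(df, feature_kind, n_total, n_retained,
                              meta = list()) {
  structure(df,
            class = c("beat_features", class(tibble())),
            feature_kind = feature_kind,
            n_total = as.integer(n_total),
            n_retained = as.integer(n_retained),
            meta = meta)
}

#' Feature kind and retention bookkeeping of a feature table
#'
#' @param features A `beat_features` tibble.
#' @return `feature_kind()` returns the kind string; `retention()` a one-row
#'   tibble with `feature_kind`, `n_total`, `n_retained` and the retention
#'   fraction.
#' @export
feature_kind <- function(features) attr(features, "feature_kind")

#' @rdname feature_kind
#' @export
retention <- function(features) {
  tibble(feature_kind = attr(features, "feature_kind"),
         n_total = attr(features, "n_total"),
         n_retained = attr(features, "n_retained"),
         retention = attr(features, "n_retained") / attr(features, "n_total"))
}

feature_columns <- function(features) {
  setdiff(names(features), c("beat", "label", "r_index"))
}

#' Numeric matrix of the feature columns
#'
#' Strips the bookkeeping columns (`beat`, `r_index`, `label`) and returns
#' the per-beat feature rows as a numeric matrix, in table order.
#'
#' @param features A `beat_features` tibble.
#' @return Numeric matrix, one row per retained beat.
#' @export
feature_matrix <- function(features) {
  as.matrix(as.data.frame(features)[, feature_columns(features), drop = FALSE])
}

#' RR intervals from an R-peak sequence
#'
#' @param peaks Strictly increasing R-peak sample indices (or a tibble with a
#'   `sample` column as returned by the detectors).
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of intervals in seconds, one fewer than the number
#'   of peaks; interval `j` spans peaks `j` and `j + 1`.
#' @export
rr_intervals <- function(peaks, fs) {
  idx <- peak_indices(peaks)
  check_scalar(fs, "fs")
  if (length(idx) < 2) {
    stop_ecg("Need at least 2 peaks to form an RR interval.",
             class = "ecgbeat_validation_error")
  }
  if (any(diff(idx) <= 0)) {
    stop_ecg("Peak indices must be strictly increasing.",
             class = "ecgbeat_validation_error")
  }
  diff(idx) / fs
}

peak_indices <- function(peaks) {
  if (is.data.frame(peaks)) as.integer(peaks$sample) else as.integer(peaks)
}

#' Rolling RR statistics over the preceding window
#'
#' For interval position `i`, the mean and population standard deviation of
#' the `window` intervals strictly before it (positions `i - window` to
#' `i - 1`). Positions without a full window of history are flagged invalid.
#'
#' @param rr Numeric RR intervals in seconds.
#' @param window Window length in beats (default 42).
#' @return A tibble with `avg_rr`, `sd_rr` and `valid`, one row per interval.
#' @export
rolling_rr_stats <- function(rr, window = 42L) {
  n <- length(rr)
  cs <- c(0, cumsum(rr))
  cs2 <- c(0, cumsum(rr^2))
  avg <- rep(NA_real_, n); sdv <- rep(NA_real_, n)
  i <- seq_len(n)
  ok <- i > window
  if (any(ok)) {
    hi <- i[ok] - 1L; lo <- i[ok] - window
    s <- cs[hi + 1L] - cs[lo]
    s2 <- cs2[hi + 1L] - cs2[lo]
    avg[ok] <- s / window
    sdv[ok] <- sqrt(pmax(s2 / window - (s / window)^2, 0))
  }
  tibble(avg_rr = avg, sd_rr = sdv, valid = ok)
}

#' RR-interval feature table
#'
#' Builds the nine temporal features per beat: the current, previous and next
#' RR interval; each of the three normalised by the rolling mean of the 42
#' preceding intervals; previous and next normalised by the current interval;
#' and the standardised current interval
#' `t_rr0 = (rr0 - avg_rr) / sd_rr`. A beat is retained only when its
#' previous and next beats exist and a full 42-interval history precedes its
#' current interval; dropped beats are counted in the retention bookkeeping.
#'
#' @param peaks R-peak sample indices (vector or detector tibble).
#' @param labels AAMI class per peak, aligned with `peaks`.
#' @param fs Sampling rate in Hz.
#' @param window Rolling-window length in beats.
#' @return A `beat_features` tibble (kind `"rri"`) with columns `beat`,
#'   `label` and the nine feature columns.
#' @export
rri_features <- function(peaks, labels, fs, window = 42L) {
  idx <- peak_indices(peaks)
  n_beats <- length(idx)
  if (!is.null(labels) && length(labels) != n_beats) {
    stop_ecg("`labels` must align with `peaks`.",
             class = "ecgbeat_validation_error")
  }
  rr <- rr_intervals(idx, fs)
  stats <- rolling_rr_stats(rr, window)
  # beat i: current interval ends at peak i, so rr0 = rr[i - 1]
  i <- seq_len(n_beats)
  keep <- i >= window + 2L & i >= 3L & i <= n_beats - 1L
  i <- i[keep]
  rr0 <- rr[i - 1L]; rr_prev <- rr[i - 2L]; rr_next <- rr[i]
  avg <- stats$avg_rr[i - 1L]; sdv <- stats$sd_rr[i - 1L]
  t_rr0 <- ifelse(sdv > 0, (rr0 - avg) / sdv, 0)
  out <- tibble(
    beat = i,
    label = if (is.null(labels)) as_aami_factor(rep(NA, length(i)))
            else as_aami_factor(labels)[i],
    rr0 = rr0, rr_prev = rr_prev, rr_next = rr_next,
    rr0_over_avg = rr0 / avg, t_rr0 = t_rr0,
    rr_prev_over_avg = rr_prev / avg, rr_prev_over_rr0 = rr_prev / rr0,
    rr_next_over_avg = rr_next / avg, rr_next_over_rr0 = rr_next / rr0
  )
  new_beat_features(out, "rri", n_total = n_beats, n_retained = nrow(out),
                    meta = list(fs = fs, window = window))
}

#' Morphology segments around corrected R peaks
#'
#' Cuts a fixed window of `w_left` samples before to `w_right` samples after
#' each R peak from the conditioned signal (defaults give a 181-sample,
#' roughly 500 ms window at 360 Hz). Beats whose window crosses a record
#' boundary are dropped and counted.
#'
#' @param signal Conditioned (resampled, denoised, baseline-free, z-scored)
#'   signal.
#' @param peaks Corrected R-peak sample indices (vector or detector tibble).
#' @param labels AAMI class per peak, or `NULL`.
#' @param w_left,w_right Window margins in samples.
#' @return A `beat_features` tibble (kind `"morphology"`) with columns
#'   `beat`, `r_index`, `label` and sample columns `s1..s<len>`.
#' @export
segment_beats <- function(signal, peaks, labels = NULL,
                          w_left = 90L, w_right = 90L) {
  check_numeric_signal(signal)
  idx <- peak_indices(peaks)
  n_beats <- length(idx)
  if (!is.null(labels) && length(labels) != n_beats) {
    stop_ecg("`labels` must align with `peaks`.",
             class = "ecgbeat_validation_error")
  }
  keep <- idx - w_left >= 1L & idx + w_right <= length(signal)
  kept <- which(keep)
  len <- w_left + w_right + 1L
  X <- matrix(0, nrow = length(kept), ncol = len,
              dimnames = list(NULL, paste0("s", seq_len(len))))
  for (r in seq_along(kept)) {
    X[r, ] <- signal[(idx[kept[r]] - w_left):(idx[kept[r]] + w_right)]
  }
  out <- dplyr::bind_cols(
    tibble(beat = kept, r_index = idx[kept],
           label = if (is.null(labels)) as_aami_factor(rep(NA, length(kept)))
                   else as_aami_factor(labels)[kept]),
    as_tibble(X))
  new_beat_features(out, "morphology", n_total = n_beats,
                    n_retained = nrow(out),
                    meta = list(w_left = w_left, w_right = w_right))
}

#' Wavelet features of beat segments
#'
#' Decomposes each morphology segment with the discrete wavelet transform
#' and keeps only the approximation coefficients at the deepest level, the
#' low-pass summary that carries the dominant beat shape. Coefficient
#' vectors are zero-padded (or truncated) to `length_out` so every row has
#' the model input length. Retention is identical to the segment table.
#'
#' @param segments A morphology `beat_features` table from [segment_beats()].
#' @param wavelet Wavelet name.
#' @param level Decomposition depth.
#' @param length_out Fixed output length of each coefficient row.
#' @return A `beat_features` tibble (kind `"wavelet"`) with columns `beat`,
#'   `r_index`, `label` and coefficient columns `c1..c<length_out>`.
#' @export
wavelet_features <- function(segments, wavelet = "db8", level = 1L,
                             length_out = 100L) {
  if (!identical(feature_kind(segments), "morphology")) {
    stop_ecg("`segments` must be a morphology feature table.",
             class = "ecgbeat_validation_error")
  }
  X <- feature_matrix(segments)
  coefs <- t(apply(X, 1, function(row) {
    a <- dwt_decompose(row, wavelet, level)$a
    if (length(a) >= length_out) a[seq_len(length_out)]
    else c(a, numeric(length_out - length(a)))
  }))
  colnames(coefs) <- paste0("c", seq_len(length_out))
  out <- dplyr::bind_cols(
    tibble(beat = segments$beat, r_index = segments$r_index,
           label = segments$label),
    as_tibble(coefs))
  new_beat_features(out, "wavelet",
                    n_total = attr(segments, "n_total"),
                    n_retained = nrow(out),
                    meta = list(wavelet = wavelet, level = level,
                                length_out = length_out))
}

#' Linearly resample each feature row to a new length
#'
#' Bridges the raw 181-sample morphology segment to the network input length
#' (100 by default elsewhere) by per-row linear interpolation.
#'
#' @param features A `beat_features` tibble.
#' @param length_out Target row length.
#' @return A `beat_features` tibble of the same kind with resampled rows.
#' @export
resample_beat_matrix <- function(features, length_out = 100L) {
  X <- feature_matrix(features)
  Y <- t(apply(X, 1, function(row) stats::approx(seq_along(row), row,
                                                 n = length_out)$y))
  colnames(Y) <- paste0("s", seq_len(length_out))
  keep <- intersect(c("beat", "r_index", "label"), names(features))
  out <- dplyr::bind_cols(as_tibble(as.data.frame(features)[, keep, drop = FALSE]),
                          as_tibble(Y))
  meta <- attr(features, "meta")
  meta$resampled_to <- length_out
  new_beat_features(out, feature_kind(features),
                    n_total = attr(features, "n_total"),
                    n_retained = nrow(out), meta = meta)
}
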