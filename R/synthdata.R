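# Synthetic single-lead ECG with known ground truth, so every downstream
# stage (denoising, baseline removal, QRS detection, feature extraction,
# model training, streaming) can be exercised without any recorded dataset.

#' Per-class beat template parameters
#'
#' Gaussian-bump templates for the five AAMI classes: a P wave, a tall narrow
#' R wave flanked by small Q/S deflections, and a wide low T wave. The
#' classes follow clinical archetypes closely enough to be separable:
#' ventricular beats (V) are wide, tall and have an inverted T wave and no P
#' wave; supraventricular beats (S) shorten their preceding RR interval
#' (`rr_scale`); fusion beats (F) sit midway between N and V; unknown beats
#' (Q) are low-amplitude and featureless.
#'
#' @return A tibble with one row per class: `class`, `p_amp`, `qrs_amp`
#'   (mV), `qrs_width` (s, total width of the R bump), `t_amp` (signed mV),
#'   `polarity`, `rr_scale`.
#' @export
beat_templates <- function() {
  tibble(
    class     = aami_classes(),
    p_amp     = c(0.12, 0.05, 0.00, 0.06,  0.00),
    qrs_amp   = c(1.00, 0.95, 1.35, 1.18,  0.45),
    qrs_width = c(0.08, 0.07, 0.14, 0.11,  0.10),
    t_amp     = c(0.30, 0.25, -0.40, -0.05, 0.10),
    polarity  = c(1, 1, 1, 1, 1),
    rr_scale  = c(1, 0.6, 1, 1, 1)
  )
}

# Evaluate one beat template on a time axis centred at the R peak.
beat_waveform <- function(t_rel, tpl) {
  gauss <- function(t, amp, mu, sd) amp * exp(-((t - mu)^2) / (2 * sd^2))
  r_sd <- tpl$qrs_width / 4
  w <- gauss(t_rel, tpl$qrs_amp, 0, r_sd) +
    gauss(t_rel, -0.15 * tpl$qrs_amp, -tpl$qrs_width / 2, r_sd / 2) +  # Q
    gauss(t_rel, -0.12 * tpl$qrs_amp,  tpl$qrs_width / 2, r_sd / 2) +  # S
    gauss(t_rel, tpl$p_amp, -0.16, 0.025) +                            # P
    gauss(t_rel, tpl$t_amp,  0.30, 0.07)                               # T
  tpl$polarity * w
}

#' Synthetic record configuration
#'
#' Conditions under which a synthetic ECG record is generated. The defaults
#' describe a realistic resting recording: mean RR of 0.8 s with mild
#' sinus-arrhythmia jitter, a class mix dominated by normal beats in
#' proportions typical of ambulatory arrhythmia data, broadband noise two
#' orders of magnitude below the R amplitude, and sub-0.5 Hz respiratory
#' baseline wander.
#'
#' @param duration Record length in seconds.
#' @param fs Sampling rate in Hz (130 and 360 are the supported rates).
#' @param rr_mean Mean RR interval in seconds, in `[0.6, 1]`.
#' @param rr_jitter_sd Standard deviation of the RR jitter in seconds.
#' @param class_mix Named probability vector over the five AAMI classes;
#'   must sum to 1 within 1e-9.
#' @param hf_noise_sd Standard deviation of additive Gaussian noise (mV).
#' @param baseline_amplitude,baseline_freq Sinusoidal baseline-wander
#'   amplitude (mV) and frequency (Hz, below 0.5).
#' @param seed Integer seed; records are bit-for-bit reproducible.
#' @param t_first Time of the first R peak in seconds (kept away from the
#'   record start so full morphology windows exist for every beat).
#' @param t_margin Seconds kept free of beats at the record end, so the last
#'   T wave and segmentation window fit.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(duration = 60, fs = 360, rr_mean = 0.8,
                         rr_jitter_sd = 0.04,
                         class_mix = c(N = 0.894, S = 0.028, V = 0.070,
                                       F = 0.0078, Q = 0.0002),
                         hf_noise_sd = 0.02, baseline_amplitude = 0.1,
                         baseline_freq = 0.3, seed = 1L,
                         t_first = 1, t_margin = 0.5) {
  check_scalar(duration, "duration"); check_scalar(fs, "fs")
  check_scalar(rr_mean, "rr_mean")
  if (rr_mean < 0.6 || rr_mean > 1) {
    stop_ecg("`rr_mean` must lie in [0.6, 1] seconds.",
             class = "ecgbeat_validation_error")
  }
  if (!setequal(names(class_mix), aami_classes()) ||
      abs(sum(class_mix) - 1) > 1e-9 || any(class_mix < 0)) {
    stop_ecg("`class_mix` must be a probability vector named N, S, V, F, Q summing to 1.",
             class = "ecgbeat_validation_error")
  }
  if (baseline_freq >= 0.5) {
    stop_ecg("`baseline_freq` must be below 0.5 Hz.",
             class = "ecgbeat_validation_error")
  }
  structure(list(duration = duration, fs = fs, rr_mean = rr_mean,
                 rr_jitter_sd = rr_jitter_sd,
                 class_mix = class_mix[aami_classes()],
                 hf_noise_sd = hf_noise_sd,
                 baseline_amplitude = baseline_amplitude,
                 baseline_freq = baseline_freq, seed = as.integer(seed),
                 t_first = t_first, t_margin = t_margin),
            class = "synth_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic ECG record
#'
#' Places beats at cumulative RR times drawn from a truncated normal
#' distribution, draws each beat's class from the configured mix (shortening
#' the RR interval preceding S beats), sums the class templates, and adds
#' Gaussian high-frequency noise and a sinusoidal baseline. The clean, noise
#' and baseline components are stored alongside the composite signal so that
#' denoising and baseline-removal stages can be tested against truth.
#'
#' @param config A [synth_config()].
#' @param templates Template table, see [beat_templates()].
#' @return An object of class `ecg_record`: list with `signal` (mV),
#'   `fs`, `rpeaks` (1-based sample indices of the true R peaks, strictly
#'   increasing), `labels` (AAMI factor, one per beat), `components` (tibble
#'   of clean/noise/baseline), and `record_id`.
#' @export
synth_record <- function(config = synth_config(), templates = beat_templates()) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  fs <- config$fs
  n <- as.integer(round(config$duration * fs))
  with_seed(config$seed, {
    n_max <- as.integer(ceiling(config$duration / 0.2)) + 2L
    rr <- rnorm(n_max, config$rr_mean, config$rr_jitter_sd)
    rr <- pmax(rr, 0.2)  # truncate at the physiological refractory floor
    cls <- sample(aami_classes(), n_max, replace = TRUE, prob = config$class_mix)
    scale <- templates$rr_scale[match(cls, templates$class)]
    rr <- rr * scale     # S beats arrive early: shorten their preceding RR
    t_beats <- config$t_first + c(0, cumsum(rr[-n_max]))
    keep <- t_beats < config$duration - config$t_margin
    t_beats <- t_beats[keep]; cls <- cls[keep]
    if (length(t_beats) == 0) {
      stop_ecg("Configuration yields no beats; increase `duration`.",
               class = "ecgbeat_validation_error")
    }
    t_axis <- (seq_len(n) - 1) / fs
    clean <- numeric(n)
    for (i in seq_along(t_beats)) {
      tpl <- templates[templates$class == cls[i], ]
      lo <- max(1L, as.integer(floor((t_beats[i] - 0.45) * fs)) + 1L)
      hi <- min(n, as.integer(ceiling((t_beats[i] + 0.55) * fs)) + 1L)
      idx <- lo:hi
      clean[idx] <- clean[idx] + beat_waveform(t_axis[idx] - t_beats[i], tpl)
    }
    noise <- if (config$hf_noise_sd > 0) rnorm(n, 0, config$hf_noise_sd) else numeric(n)
    baseline <- if (config$baseline_amplitude > 0) {
      config$baseline_amplitude * sin(2 * pi * config$baseline_freq * t_axis)
    } else numeric(n)
    structure(
      list(signal = clean + noise + baseline, fs = fs,
           rpeaks = as.integer(round(t_beats * fs)) + 1L,
           labels = as_aami_factor(cls),
           components = tibble(clean = clean, noise = noise, baseline = baseline),
           record_id = sprintf("synth-%d", config$seed),
           config = config),
      class = "ecg_record")
  })
}

#' Decompose a synthetic record into its stored components
#'
#' @param record An `ecg_record` produced by [synth_record()].
#' @return A tibble with `time_s`, `clean`, `noise`, `baseline`; the three
#'   components sum to the record's signal exactly.
#' @export
decompose_record <- function(record) {
  if (!inherits(record, "ecg_record") || is.null(record$components)) {
    stop_ecg("`record` must be a synthetic record with stored components.",
             class = "ecgbeat_validation_error")
  }
  dplyr::mutate(record$components,
                time_s = (seq_len(length(record$signal)) - 1) / record$fs,
                .before = 1)
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s: %.1f s at %g Hz, %d beats>\n",
              x$record_id %||% "?", length(x$signal) / x$fs, x$fs,
              length(x$rpeaks)))
  if (length(x$labels)) print(table(x$labels))
  invisible(x)
}

#' @export
tidy.ecg_record <- function(x, ...) {
  tibble(time_s = (seq_along(x$signal) - 1) / x$fs, mv = x$signal)
}

#' Separable synthetic feature set for classifier checks
#'
#' Builds a labelled per-beat feature table in which each class is a noisy
#' copy of its (z-scored) template waveform sampled at `input_length` points.
#' At the default noise level the classes are fully separable (a
#' nearest-template classifier is exact), which is the point: the set
#' verifies that each architecture can learn at all, it does not emulate
#' real inter-class difficulty.
#'
#' @param n Number of beats.
#' @param input_length Feature length (e.g. 9 for RR-style input, 100 for
#'   segment-style input).
#' @param noise_sd Within-class Gaussian noise, in units of the z-scored
#'   template.
#' @param class_mix Named class probabilities (balanced by default).
#' @param seed Integer seed.
#' @return A `beat_features` tibble with a `label` column and feature columns
#'   `x1..x<input_length>`.
#' @export
synth_separable_features <- function(n = 5000, input_length = 9,
                                     noise_sd = 0.05,
                                     class_mix = c(N = 0.2, S = 0.2, V = 0.2,
                                                   F = 0.2, Q = 0.2),
                                     seed = 1L) {
  templates <- beat_templates()
  t_rel <- seq(-0.25, 0.55, length.out = 361)
  means <- lapply(seq_len(nrow(templates)), function(i) {
    w <- beat_waveform(t_rel, templates[i, ])
    w <- stats::approx(seq_along(w), w, n = input_length)$y
    (w - mean(w)) / sqrt(mean((w - mean(w))^2))
  })
  names(means) <- templates$class
  with_seed(seed, {
    cls <- sample(aami_classes(), n, replace = TRUE,
                  prob = class_mix[aami_classes()])
    X <- t(vapply(cls, function(cl) means[[cl]] + rnorm(input_length, 0, noise_sd),
                  numeric(input_length)))
    out <- as_tibble(as.data.frame(X), .name_repair = ~ paste0("x", seq_len(input_length)))
    out <- dplyr::mutate(out, label = as_aami_factor(cls), .before = 1)
    new_beat_features(out, feature_kind = "synthetic",
                      n_total = n, n_retained = n)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
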