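test_that("noiseless periodic records place beats deterministically", {
  cfg <- synth_config(duration = 60, fs = 360, rr_mean = 1.0,
                      rr_jitter_sd = 0, hf_noise_sd = 0,
                      baseline_amplitude = 0, seed = 1,
                      class_mix = c(N = 1, S = 0, V = 0, F = 0, Q = 0))
  rec <- synth_record(cfg)
  # first beat at t_first = 1 s, then every rr_mean until the end margin
  expected_times <- seq(1, 60 - cfg$t_margin - 1e-9, by = 1.0)
  expect_equal(length(rec$rpeaks), length(expected_times))
  expect_equal(rec$rpeaks, as.integer(round(expected_times * 360)) + 1L)
  expect_true(all(rec$labels == "N"))

  cfg2 <- synth_config(duration = 60, fs = 360, rr_mean = 0.75,
                       rr_jitter_sd = 0, hf_noise_sd = 0,
                       baseline_amplitude = 0, seed = 1,
                       class_mix = c(N = 1, S = 0, V = 0, F = 0, Q = 0))
  rec2 <- synth_record(cfg2)
  # same cumulative construction as the generator (guards float accumulation)
  times <- 1 + c(0, cumsum(rep(0.75, 400)))
  expect_equal(length(rec2$rpeaks), sum(times < 60 - cfg2$t_margin))
})

test_that("identical configs and seeds give bit-identical records", {
  cfg <- synth_config(duration = 30, seed = 42)
  a <- synth_record(cfg)
  b <- synth_record(cfg)
  expect_identical(a$signal, b$signal)
  expect_identical(a$rpeaks, b$rpeaks)
  expect_identical(a$labels, b$labels)
})

test_that("decompose_record reproduces the signal additively", {
  rec <- synth_record(synth_config(duration = 30, hf_noise_sd = 0.05,
                                   baseline_amplitude = 0.2, seed = 5))
  parts <- decompose_record(rec)
  expect_lt(max(abs(parts$clean + parts$noise + parts$baseline - rec$signal)),
            1e-12)
  # noiseless / baseline-free configs give identically zero components
  rec0 <- synth_record(synth_config(duration = 20, hf_noise_sd = 0,
                                    baseline_amplitude = 0, seed = 5))
  parts0 <- decompose_record(rec0)
  expect_identical(unique(parts0$noise), 0)
  expect_identical(unique(parts0$baseline), 0)
})

test_that("class templates are mutually separable on noiseless segments", {
  templates <- beat_templates()
  rec <- synth_record(synth_config(
    duration = 300, fs = 360, rr_mean = 1.0, rr_jitter_sd = 0,
    class_mix = c(N = 0.2, S = 0.2, V = 0.2, F = 0.2, Q = 0.2),
    hf_noise_sd = 0, baseline_amplitude = 0, seed = 9))
  seg <- segment_beats(rec$signal, rec$rpeaks, rec$labels)
  X <- feature_matrix(seg)
  # nearest-template assignment on raw noiseless segments must be exact
  t_rel <- (seq_len(181) - 91) / 360
  means <- vapply(seq_len(5), function(i) {
    ecgbeat:::beat_waveform(t_rel, templates[i, ])
  }, numeric(181))
  pred <- aami_classes()[apply(X, 1, function(r) {
    which.min(colSums((means - r)^2))
  })]
  expect_true(all(pred == as.character(seg$label)))
  expect_setequal(unique(as.character(seg$label)), aami_classes())
})

test_that("invalid class mixes are rejected", {
  expect_error(synth_config(class_mix = c(N = 0.5, S = 0.2, V = 0.2,
                                          F = 0.05, Q = 0.1)),
               class = "ecgbeat_validation_error")
  expect_error(synth_config(rr_mean = 1.4),
               class = "ecgbeat_validation_error")
})

test_that("separable feature sets are reproducible and fully separable", {
  a <- synth_separable_features(500, input_length = 9, seed = 4)
  b <- synth_separable_features(500, input_length = 9, seed = 4)
  expect_identical(feature_matrix(a), feature_matrix(b))
  expect_equal(retention(a)$retention, 1)
  expect_setequal(unique(as.character(a$label)), aami_classes())
})
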