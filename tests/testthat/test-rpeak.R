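test_that("Pan-Tompkins finds essentially every beat on clean records", {
  rec <- clean_record()
  pp <- preprocess_signal(rec$signal, rec$fs)
  det <- pan_tompkins(pp$signal, pp$fs)
  m <- match_rpeaks(det, rec$rpeaks, rec$fs, tol_s = 0.05)
  expect_gte(m$sensitivity, 0.99)
  expect_gte(m$ppv, 0.99)
  # minimum RR gap respects the refractory period
  expect_true(all(diff(det$sample) > 0.2 * pp$fs))
})

test_that("detection degrades gracefully under noise and rejects bad input", {
  rec <- synth_record(synth_config(duration = 90, fs = 360, rr_mean = 0.75,
                                   rr_jitter_sd = 0.03, hf_noise_sd = 0.05,
                                   baseline_amplitude = 0.15, seed = 8))
  pp <- preprocess_signal(rec$signal, rec$fs)
  m <- match_rpeaks(pan_tompkins(pp$signal, pp$fs), rec$rpeaks, rec$fs)
  expect_gte(m$sensitivity, 0.95)
  expect_gte(m$ppv, 0.95)

  expect_identical(nrow(pan_tompkins(numeric(1000), 360)), 0L)
  expect_error(pan_tompkins(rnorm(100), 360), class = "ecgbeat_validation_error")
  expect_error(pan_tompkins(rnorm(1000), 50), class = "ecgbeat_validation_error")
})

test_that("peak correction finds local maxima, ties and fixed points", {
  sig <- numeric(200)
  sig[100] <- 1                      # isolated peak
  cor1 <- correct_rpeaks(sig, 93L)   # offset -7
  expect_identical(cor1$sample, 100L)
  expect_identical(correct_rpeaks(sig, 100L)$sample, 100L)  # fixed point
  # two equal maxima in the window: earliest wins
  sig2 <- numeric(100); sig2[c(40, 50)] <- 1
  expect_identical(correct_rpeaks(sig2, 45L)$sample, 40L)
  # colliding corrections are merged keeping one index
  expect_identical(correct_rpeaks(sig, c(95L, 105L))$sample, 100L)
})

test_that("correction is idempotent and bounded on synthetic data", {
  rec <- clean_record()
  pp <- preprocess_signal(rec$signal, rec$fs)
  ann <- rpeak_set(rec$rpeaks, rec$fs)
  cor1 <- correct_rpeaks(pp$signal, ann, w_corr = 20)
  cor2 <- correct_rpeaks(pp$signal, cor1, w_corr = 20)
  expect_identical(cor1$sample, cor2$sample)
  moved <- abs(cor1$sample - rec$rpeaks[seq_len(nrow(cor1))])
  expect_true(all(moved <= 20))
})

test_that("detected and annotated peaks agree after the full chain", {
  rec <- clean_record()
  pp <- preprocess_signal(rec$signal, rec$fs)
  det <- correct_rpeaks(pp$signal, pan_tompkins(pp$signal, pp$fs))
  m <- match_rpeaks(det, rec$rpeaks, rec$fs, tol_s = 0.05)
  expect_gte(m$sensitivity, 0.99)
})
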