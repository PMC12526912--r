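test_that("RR intervals are plain first differences in seconds", {
  expect_equal(rr_intervals(c(1L, 361L, 721L), 360), c(1, 1))
  expect_equal(rr_intervals(c(1L, 271L, 721L), 360), c(0.75, 1.25))
  expect_error(rr_intervals(c(100L), 360), class = "ecgbeat_validation_error")
  expect_error(rr_intervals(c(100L, 90L, 200L), 360),
               class = "ecgbeat_validation_error")
})

test_that("rolling RR statistics use exactly the preceding window", {
  rr <- rep(0.8, 60)
  st <- rolling_rr_stats(rr, 42)
  expect_false(any(st$valid[1:42]))
  expect_true(all(st$valid[43:60]))
  expect_equal(st$avg_rr[43:60], rep(0.8, 18))
  expect_equal(st$sd_rr[43:60], rep(0, 18))

  rr2 <- rep(c(0.6, 1.0), 30)
  st2 <- rolling_rr_stats(rr2, 42)
  expect_equal(st2$avg_rr[43], 0.8)
  expect_equal(st2$sd_rr[43], 0.2)    # closed form for the two-point alternation

  expect_false(any(rolling_rr_stats(rep(0.8, 41), 42)$valid))
})

test_that("perfectly periodic records give unit ratios and zero t_rr0", {
  peaks <- seq(1L, by = 270L, length.out = 100L)
  labels <- rep("N", 100)
  fm <- rri_features(peaks, labels, 360)
  X <- feature_matrix(fm)
  ratio_cols <- c("rr0_over_avg", "rr_prev_over_avg", "rr_prev_over_rr0",
                  "rr_next_over_avg", "rr_next_over_rr0")
  for (cl in ratio_cols) expect_equal(unname(X[, cl]), rep(1, nrow(X)))
  expect_equal(unname(X[, "t_rr0"]), rep(0, nrow(X)))
  # drops the first 43 beats (window + current-interval history) and the
  # final beat (no next interval)
  expect_equal(retention(fm)$n_total, 100L)
  expect_equal(retention(fm)$n_retained, 100L - 44L)
  expect_identical(fm$beat, 44:99)
})

test_that("rri_features matches the brute-force per-beat oracle", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample(50:140, 1)
    rr <- pmax(rnorm(n - 1, 0.8, 0.12), 0.3)
    peaks <- as.integer(round(cumsum(c(1, rr * 360))))
    fm <- rri_features(peaks, rep("N", n), 360)
    oracle <- brute_force_rri(peaks, NULL, 360)
    if (is.null(oracle)) {
      expect_identical(nrow(fm), 0L)
      next
    }
    expect_identical(fm$beat, oracle$beat)
    for (cl in setdiff(names(oracle), "beat")) {
      expect_equal(unname(feature_matrix(fm)[, cl]), oracle[[cl]],
                   tolerance = 1e-12)
    }
  }
})

test_that("ratio features are invariant to a global time rescaling", {
  peaks <- as.integer(round(cumsum(c(1, pmax(rnorm(99, 0.8, 0.1), 0.3) * 360))))
  a <- feature_matrix(rri_features(peaks, NULL, 360))
  b <- feature_matrix(rri_features(peaks, NULL, 120))   # all RR scaled by 3
  inv <- c("rr0_over_avg", "t_rr0", "rr_prev_over_avg", "rr_prev_over_rr0",
           "rr_next_over_avg", "rr_next_over_rr0")
  expect_equal(a[, inv], b[, inv], tolerance = 1e-9)
  expect_equal(3 * a[, "rr0"], b[, "rr0"], tolerance = 1e-9)
})

test_that("beat segmentation indexes, drops and counts correctly", {
  sig <- rnorm(2000)
  seg <- segment_beats(sig, c(50L, 1000L, 1950L), c("N", "V", "N"))
  # the first and last windows cross the record bounds and are dropped
  expect_identical(seg$beat, 2L)
  expect_identical(retention(seg)$n_total, 3L)
  expect_identical(retention(seg)$n_retained, 1L)
  expect_equal(unname(feature_matrix(seg)[1, ]), sig[910:1090])
  expect_identical(ncol(feature_matrix(seg)), 181L)
  expect_identical(as.character(seg$label), "V")
})

test_that("wavelet features mirror segment retention and pad to fixed length", {
  rec <- clean_record()
  seg <- segment_beats(rec$signal, rec$rpeaks, rec$labels)
  wf <- wavelet_features(seg, "db8", 1, length_out = 100)
  expect_identical(nrow(wf), nrow(seg))
  expect_identical(retention(wf)$n_retained, retention(seg)$n_retained)
  expect_identical(ncol(feature_matrix(wf)), 100L)
  # a length-181 segment yields 98 coefficients, so the last 2 columns pad
  X <- feature_matrix(wf)
  expect_true(all(X[, 99:100] == 0))
  expect_identical(as.character(wf$label), as.character(seg$label))
})

test_that("segment resampling preserves rows and hits the target length", {
  rec <- clean_record()
  seg <- segment_beats(rec$signal, rec$rpeaks, rec$labels)
  rs <- resample_beat_matrix(seg, 100)
  expect_identical(nrow(rs), nrow(seg))
  expect_identical(ncol(feature_matrix(rs)), 100L)
  expect_identical(feature_kind(rs), "morphology")
})
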