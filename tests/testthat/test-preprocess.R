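test_that("resampling is the identity at equal rates and near-exact on band-limited signals", {
  x <- rnorm(500)
  expect_lt(max(abs(resample_signal(x, 360, 360) - x)), 1e-9)

  t130 <- seq(0, 10 - 1 / 130, by = 1 / 130)
  s <- sin(2 * pi * t130)
  r <- resample_signal(s, 130, 360)
  expect_length(r, 3600)
  t360 <- seq(0, by = 1 / 360, length.out = 3600)
  interior <- 200:3400
  expect_lt(max(abs(r[interior] - sin(2 * pi * t360[interior]))), 1e-3)

  expect_length(resample_signal(rnorm(1300), 130, 360), 3600)
  expect_error(resample_signal(c(1, NA, 3), 130, 360),
               class = "ecgbeat_validation_error")
})

test_that("soft thresholding and denoising behave as defined", {
  expect_equal(ecgbeat:::soft_threshold(3, 1), 2)
  expect_equal(ecgbeat:::soft_threshold(-0.5, 1), 0)
  expect_equal(ecgbeat:::soft_threshold(-3, 1), -2)

  expect_identical(wavelet_denoise(numeric(512), levels = 3), numeric(512))

  set.seed(31)
  t <- seq(0, 4, length.out = 2048)
  clean <- sin(2 * pi * 1.5 * t)
  noisy <- clean + rnorm(2048, 0, 0.1)
  den <- suppressWarnings(wavelet_denoise(noisy, "db8", 10))
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rmse(den, clean), rmse(noisy, clean))
  expect_length(den, 2048)
})

test_that("denoising depth is clamped with a warning on short signals", {
  expect_warning(wavelet_denoise(rnorm(128), "db8", 10), "Clamping")
})

test_that("median filter matches brute force and rejects impulses", {
  expect_equal(median_filter_1d(rep(2, 50), 7), rep(2, 50))
  expect_equal(median_filter_1d(c(1, 5, 2, 8, 3), 3),
               brute_force_median(c(1, 5, 2, 8, 3), 3))
  x <- rep(1, 30); x[14] <- 50
  expect_equal(median_filter_1d(x, 3), rep(1, 30))
  expect_error(median_filter_1d(rnorm(10), 4),
               class = "ecgbeat_validation_error")
  expect_error(median_filter_1d(rnorm(10), 21),
               class = "ecgbeat_validation_error")
})

test_that("baseline removal recovers slow trends and is exactly additive", {
  fs <- 360
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  slow <- sin(2 * pi * 0.2 * t)
  bw <- remove_baseline(slow)
  n <- length(slow)
  interior <- 216:(n - 216)   # reflect padding blurs the outermost window
  expect_lt(max(abs(bw$corrected[interior])), 0.1)
  expect_lt(max(abs(bw$corrected + bw$trend - slow)), 1e-12)

  const <- rep(3.7, 1000)
  bw2 <- remove_baseline(const)
  expect_lt(max(abs(bw2$corrected)), 1e-12)
  expect_equal(bw2$trend, const)

  rec <- synth_record(synth_config(duration = 60, fs = 360,
                                   baseline_amplitude = 0.25,
                                   baseline_freq = 0.25,
                                   hf_noise_sd = 0, seed = 13))
  parts <- decompose_record(rec)
  trend <- remove_baseline(rec$signal)$trend
  expect_gt(cor(trend, parts$baseline), 0.95)
  expect_error(remove_baseline(rnorm(100)), class = "ecgbeat_validation_error")
})

test_that("baseline removal preserves QRS timing on clean beats", {
  rec <- clean_record()
  bw <- remove_baseline(rec$signal)
  # the global argmax may move between equal-height beats, but it must stay
  # within two samples of *an* R peak
  nearest <- min(abs(which.max(bw$corrected) - rec$rpeaks))
  expect_lte(nearest, 2)
  expect_lte(min(abs(which.max(rec$signal) - rec$rpeaks)), 2)
})

test_that("z-score normalisation is exact, idempotent and guarded", {
  expect_equal(zscore(c(0, 1)), c(-1, 1))
  x <- c(2, 4, 4, 4, 5, 5, 7, 9)
  z <- zscore(x)
  expect_equal(z[1], -1.5)   # mu = 5, population sd = 2
  y <- rnorm(100)
  expect_lt(abs(mean(zscore(y))), 1e-9)
  expect_lt(abs(sqrt(mean(zscore(y)^2)) - 1), 1e-9)
  expect_lt(max(abs(zscore(zscore(y)) - zscore(y))), 1e-9)
  expect_error(zscore(rep(1, 10)), class = "ecgbeat_validation_error")
})
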