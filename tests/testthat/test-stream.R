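# Streaming tests use a 90 s record and a small trained model; the
# five-minute equivalence runs live in the acceptance suite.

stream_test_record <- function() {
  cached("stream_test_record", synth_record(synth_config(
    duration = 90, fs = 130, rr_mean = 0.8, rr_jitter_sd = 0.04,
    class_mix = c(N = 0.7, S = 0.1, V = 0.1, F = 0.05, Q = 0.05),
    hf_noise_sd = 0.02, baseline_amplitude = 0.1, seed = 21)))
}

test_that("emission is monotone and deterministic", {
  m <- tiny_wavelet_model()
  rec <- stream_test_record()
  sess <- stream_record_through(m, rec, chunk_s = 1)
  preds <- session_predictions(sess)
  expect_gt(nrow(preds), 50)
  expect_true(all(diff(preds$beat_index) == 1))
  expect_true(all(diff(preds$r_peak_time_s) > 0))
  expect_true(all(preds$confidence >= 0.2 & preds$confidence <= 1))
  sess2 <- stream_record_through(m, rec, chunk_s = 1)
  preds2 <- session_predictions(sess2)
  expect_identical(preds$sample, preds2$sample)
  expect_identical(as.character(preds$label), as.character(preds2$label))
})

test_that("emitted labels are invariant to the chunk size", {
  m <- tiny_wavelet_model()
  rec <- stream_test_record()
  runs <- lapply(c(0.5, 1, 5), function(cs) {
    session_predictions(stream_record_through(m, rec, cs))
  })
  for (k in 2:3) {
    expect_identical(runs[[1]]$sample, runs[[k]]$sample)
    expect_identical(as.character(runs[[1]]$label),
                     as.character(runs[[k]]$label))
  }
})

test_that("streamed beats agree with the offline pipeline", {
  m <- tiny_wavelet_model()
  rec <- stream_test_record()
  batch <- classify_record(rec, model = m)
  preds <- session_predictions(stream_record_through(m, rec, 1))
  # every streamed beat corresponds to an offline beat at the same position
  j <- vapply(preds$sample, function(s) {
    d <- abs(batch$sample - s)
    w <- which.min(d)
    if (d[w] <= 5) w else NA_integer_
  }, integer(1))
  expect_true(all(!is.na(j)))
  agreement <- mean(as.character(preds$label) == as.character(batch$label[j]))
  expect_gte(agreement, 0.95)
})

test_that("latency reports summarise per-beat timings against 0.6 s", {
  m <- tiny_wavelet_model()
  sess <- stream_record_through(m, stream_test_record(), 1)
  rep <- latency_report(sess)
  expect_identical(rep$realtime_threshold_s, 0.6)
  expect_lte(rep$min_inference_s, rep$mean_inference_s)
  expect_lte(rep$mean_inference_s, rep$max_inference_s)
  expect_gte(rep$realtime_fraction, 0)
  # arithmetic of the compliance fraction on hand-built timings
  fake <- stream_session(m, fs_source = 130)
  fake$predictions <- list(tibble::tibble(
    beat_index = 1:3, sample = c(1L, 2L, 3L), r_peak_time_s = 1:3,
    label = factor(c("N", "N", "V"), levels = aami_classes()),
    confidence = rep(1, 3), inference_s = c(0.1, 0.3, 0.9),
    end_to_end_s = c(0.1, 0.3, 0.9)))
  expect_equal(latency_report(fake)$realtime_fraction, 2 / 3)
  empty <- stream_session(m, fs_source = 130)
  expect_error(latency_report(empty), class = "ecgbeat_validation_error")
})

test_that("sessions reject mismatched or malformed chunks", {
  m <- tiny_wavelet_model()
  sess <- stream_session(m, fs_source = 130)
  expect_error(ingest(sess, stream_chunk(0, 360, rnorm(10))),
               class = "ecgbeat_schema_error")
  expect_error(ingest(sess, list(samples = 1:5)),
               class = "ecgbeat_schema_error")
})

test_that("the request router serves health, sessions, stats and errors", {
  m <- tiny_wavelet_model()
  srv <- ecg_service(m, fs_source = 130)
  expect_equal(handle_request(srv, "GET", "/health")$body$status, "ok")

  r1 <- handle_request(srv, "POST", "/session")
  r2 <- handle_request(srv, "POST", "/session")
  id1 <- r1$body$session_id; id2 <- r2$body$session_id
  expect_false(identical(id1, id2))

  rec <- stream_test_record()
  recB <- synth_record(synth_config(
    duration = 30, fs = 130, rr_mean = 0.7, hf_noise_sd = 0.02, seed = 99))
  # interleave two sessions with different records: no cross-talk
  direct <- stream_session(m, fs_source = 130)
  out_http <- list()
  step <- 130L
  for (start in seq(1, 30 * 130, by = step)) {
    idx <- start:min(start + step - 1L, length(rec$signal))
    ch1 <- encode_chunk(stream_chunk(0, 130, rec$signal[idx]))
    ch2 <- encode_chunk(stream_chunk(0, 130, recB$signal[idx]))
    resp <- handle_request(srv, "POST", sprintf("/session/%s/chunk", id1), ch1)
    expect_equal(resp$status, 200L)
    out_http[[length(out_http) + 1L]] <- resp$body$predictions
    handle_request(srv, "POST", sprintf("/session/%s/chunk", id2), ch2)
    ingest(direct, stream_chunk(0, 130, rec$signal[idx]))
  }
  http_labels <- unlist(lapply(out_http, function(p) {
    vapply(p, function(b) b$label, "")
  }))
  direct_preds <- session_predictions(direct)
  expect_identical(http_labels, as.character(direct_preds$label))

  stats <- handle_request(srv, "GET", sprintf("/session/%s/stats", id1))
  expect_equal(stats$status, 200L)
  expect_equal(stats$body$n_beats, length(http_labels))

  expect_equal(handle_request(srv, "GET", "/session/nope/stats")$status, 404L)
  bad <- handle_request(srv, "POST", sprintf("/session/%s/chunk", id1),
                        "{\"fs\": 130}")
  expect_equal(bad$status, 400L)
  expect_match(bad$body$error, "samples|timestamp")
})

test_that("the TCP server answers HTTP requests like the in-process router", {
  skip_if_not_installed("callr")
  m <- tiny_wavelet_model()
  port <- 18000L + (Sys.getpid() %% 2000L)
  proc <- callr::r_bg(function(model, port) {
    library(ecgbeat)
    serve(ecg_service(model, fs_source = 130), port = port, max_requests = 2L)
  }, args = list(model = m, port = port))
  on.exit(proc$kill(), add = TRUE)
  http_get <- function(path, tries = 50) {
    for (i in seq_len(tries)) {
      res <- tryCatch({
        con <- socketConnection("127.0.0.1", port, blocking = TRUE,
                                open = "r+b", timeout = 5)
        writeLines(c(sprintf("GET %s HTTP/1.1", path), "Host: localhost",
                     "", ""), con, sep = "\r\n")
        flush(con)
        lines <- readLines(con)
        close(con)
        lines
      }, error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(res) && length(res)) return(res)
      Sys.sleep(0.2)
    }
    NULL
  }
  lines <- http_get("/health")
  expect_false(is.null(lines))
  expect_match(lines[1], "200")
  expect_match(lines[length(lines)], "\"ok\"")
})
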