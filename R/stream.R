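# Streaming inference: chunked ingestion, windowed online preprocessing,
# beat detection and deduplication across windows, per-beat classification
# with wall-clock latency accounting, and the offline batch pipeline the
# stream is checked against.
#
# Processing happens in rounds at fixed stream times (every `hop_s` seconds
# of buffered signal), independent of how the samples were chunked, so the
# emitted beats are invariant to the chunk size. Each round conditions the
# trailing `window_s` seconds, detects QRS complexes, registers previously
# unseen peaks, and emits a prediction for every registered beat that is old
# enough for its feature context (next beat, right segment margin) to exist.

feature_requirement_margin <- function(feature_kind) {
  # seconds a beat must age before its features are computable
  switch(feature_kind, rri = 1.6, 1.0)
}

beat_feature_rows <- function(signal, fs, peaks, model) {
  kind <- model$feature_kind
  if (kind %in% c("morphology", "synthetic")) {
    seg <- segment_beats(signal, peaks, NULL)
    if (nrow(seg) == 0) return(NULL)
    resample_beat_matrix(seg, model$spec$input_length)
  } else if (kind == "wavelet") {
    seg <- segment_beats(signal, peaks, NULL)
    if (nrow(seg) == 0) return(NULL)
    wavelet_features(seg, length_out = model$spec$input_length)
  } else if (kind == "rri") {
    if (length(peaks) < 45) return(NULL)
    rri_features(peaks, NULL, fs)
  } else {
    stop_ecg(sprintf("Unsupported feature kind '%s'.", kind),
             class = "ecgbeat_validation_error")
  }
}

#' Offline beat classification of a full record
#'
#' The batch reference pipeline: condition the whole signal
#' (resample, denoise, baseline removal, z-score), detect and
#' correct R peaks, extract the model's feature kind, and classify every
#' beat whose feature context exists.
#'
#' @param signal Numeric ECG signal, or an `ecg_record`.
#' @param fs Sampling rate of `signal` (ignored for records).
#' @param model A `beat_classifier`.
#' @param config A [preprocess_config()].
#' @return A tibble with `beat`, `sample` (index on the conditioned grid),
#'   `r_peak_time_s`, `label`, `confidence`.
#' @export
classify_record <- function(signal, fs = NULL, model,
                            config = preprocess_config()) {
  if (inherits(signal, "ecg_record")) {
    fs <- signal$fs; signal <- signal$signal
  }
  pp <- preprocess_signal(signal, fs, config)
  peaks <- correct_rpeaks(pp$signal, pan_tompkins(pp$signal, pp$fs))
  feats <- beat_feature_rows(pp$signal, pp$fs, peaks$sample, model)
  if (is.null(feats) || nrow(feats) == 0) {
    return(tibble(beat = integer(0), sample = integer(0),
                  r_peak_time_s = numeric(0),
                  label = as_aami_factor(character(0)),
                  confidence = numeric(0)))
  }
  pred <- predict(model, feats, type = "prob")
  probs <- as.matrix(pred[, -1, drop = FALSE])
  tibble(beat = feats$beat,
         sample = peaks$sample[feats$beat],
         r_peak_time_s = (peaks$sample[feats$beat] - 1) / pp$fs,
         label = pred$.pred_class,
         confidence = apply(probs, 1, max))
}

#' Open a streaming classification session
#'
#' @param model A fitted `beat_classifier`.
#' @param fs_source Sampling rate of the incoming chunks in Hz (130 for the
#'   wearable source emulated here).
#' @param window_s,hop_s Analysis window and hop in seconds: each time
#'   `hop_s` further seconds are buffered, the trailing `window_s` seconds
#'   are re-conditioned and newly matured beats are emitted.
#' @param config A [preprocess_config()].
#' @return A `stream_session` environment.
#' @export
stream_session <- function(model, fs_source = 130, window_s = 10, hop_s = 2,
                           config = preprocess_config()) {
  s <- new.env(parent = emptyenv())
  s$model <- model
  s$fs_source <- fs_source
  s$window_s <- window_s
  s$hop_s <- hop_s
  s$config <- config
  s$buffer <- numeric(0)
  s$next_round <- 1L
  s$peaks <- integer(0)       # registry of peak samples on the target grid
  s$emitted <- logical(0)     # parallel to s$peaks
  s$predictions <- list()
  s$n_emitted <- 0L
  class(s) <- "stream_session"
  s
}

#' @export
print.stream_session <- function(x, ...) {
  cat(sprintf("<stream_session: %.1f s buffered at %g Hz, %d beats emitted>\n",
              length(x$buffer) / x$fs_source, x$fs_source, x$n_emitted))
  invisible(x)
}

process_round <- function(session, tau) {
  fs_t <- session$config$fs_target
  t0 <- max(0, tau - session$window_s)
  i0 <- as.integer(round(t0 * session$fs_source))
  i1 <- as.integer(round(tau * session$fs_source))
  chunk_sig <- session$buffer[(i0 + 1L):i1]
  t_pre <- proc.time()[["elapsed"]]
  pp <- tryCatch(
    suppressWarnings(preprocess_signal(chunk_sig, session$fs_source,
                                       session$config)),
    ecgbeat_validation_error = function(e) NULL)
  if (is.null(pp)) return(NULL)
  det <- tryCatch(pan_tompkins(pp$signal, fs_t),
                  ecgbeat_validation_error = function(e) NULL)
  if (is.null(det) || nrow(det) == 0) return(NULL)
  cor <- correct_rpeaks(pp$signal, det)
  offset <- as.integer(round(t0 * fs_t))
  global <- cor$sample + offset
  refractory <- as.integer(0.2 * fs_t)
  for (g in global) {
    if (length(session$peaks) == 0 ||
        min(abs(session$peaks - g)) > refractory) {
      session$peaks <- c(session$peaks, g)
      session$emitted <- c(session$emitted, FALSE)
    }
  }
  ord <- order(session$peaks)
  session$peaks <- session$peaks[ord]
  session$emitted <- session$emitted[ord]
  pre_elapsed <- proc.time()[["elapsed"]] - t_pre

  margin <- feature_requirement_margin(session$model$feature_kind)
  mature <- (session$peaks - 1) / fs_t <= tau - margin
  todo <- which(mature & !session$emitted)
  if (length(todo) == 0) return(NULL)

  # features for every candidate beat, computed once per round
  t_feat <- proc.time()[["elapsed"]]
  local <- session$peaks - offset
  if (session$model$feature_kind == "rri") {
    feats <- beat_feature_rows(pp$signal, fs_t, session$peaks, session$model)
    registry_of_row <- if (is.null(feats)) integer(0) else feats$beat
  } else {
    in_win <- which(local >= 1L & local <= length(pp$signal))
    feats <- beat_feature_rows(pp$signal, fs_t, local[in_win], session$model)
    registry_of_row <- if (is.null(feats)) integer(0) else in_win[feats$beat]
  }
  feat_elapsed <- proc.time()[["elapsed"]] - t_feat
  rows <- match(todo, registry_of_row)
  todo <- todo[!is.na(rows)]; rows <- rows[!is.na(rows)]
  if (length(todo) == 0) return(NULL)
  X <- feature_matrix(feats)
  feat_share <- feat_elapsed / length(todo)   # feature extraction per beat
  pre_share <- pre_elapsed / length(todo)     # signal conditioning per beat
  out <- list()
  for (k in seq_along(todo)) {
    j <- todo[k]
    t_beat <- proc.time()[["elapsed"]]
    pred <- predict(session$model, X[rows[k], , drop = FALSE],
                    type = "prob", batch_size = 1L)
    inference_s <- proc.time()[["elapsed"]] - t_beat + feat_share
    session$emitted[j] <- TRUE
    session$n_emitted <- session$n_emitted + 1L
    out[[length(out) + 1L]] <- tibble(
      beat_index = session$n_emitted,
      sample = session$peaks[j],
      r_peak_time_s = (session$peaks[j] - 1) / fs_t,
      label = pred$.pred_class,
      confidence = max(as.matrix(pred[, -1, drop = FALSE])),
      inference_s = inference_s,
      end_to_end_s = inference_s + pre_share)
  }
  dplyr::bind_rows(out)
}

#' Ingest one chunk into a streaming session
#'
#' Appends the chunk's samples and runs every analysis round whose stream
#' time the buffer has now passed. Emission is deterministic given the
#' session state and invariant to how the sample stream is chunked.
#'
#' @param session A [stream_session()].
#' @param chunk A [stream_chunk()] with `fs` equal to the session source
#'   rate.
#' @return A tibble of newly emitted predictions (possibly empty) with
#'   `beat_index`, `sample`, `r_peak_time_s`, `label`, `confidence`,
#'   `inference_s`, `end_to_end_s`.
#' @export
ingest <- function(session, chunk) {
  if (!inherits(chunk, "stream_chunk")) {
    stop_ecg("`chunk` must be a stream_chunk.", class = "ecgbeat_schema_error")
  }
  if (abs(chunk$fs - session$fs_source) > 1e-9) {
    stop_ecg(sprintf("Chunk fs %g does not match session fs %g.",
                     chunk$fs, session$fs_source),
             class = "ecgbeat_schema_error")
  }
  session$buffer <- c(session$buffer, chunk$samples)
  emitted <- list()
  repeat {
    tau <- session$next_round * session$hop_s
    if (length(session$buffer) < round(tau * session$fs_source)) break
    res <- process_round(session, tau)
    if (!is.null(res)) emitted[[length(emitted) + 1L]] <- res
    session$next_round <- session$next_round + 1L
  }
  out <- if (length(emitted)) dplyr::bind_rows(emitted) else
    tibble(beat_index = integer(0), sample = integer(0),
           r_peak_time_s = numeric(0), label = as_aami_factor(character(0)),
           confidence = numeric(0), inference_s = numeric(0),
           end_to_end_s = numeric(0))
  session$predictions[[length(session$predictions) + 1L]] <- out
  out
}

#' Streaming predictions accumulated so far
#'
#' @param session A [stream_session()].
#' @return Tibble of all emitted predictions, in emission order.
#' @export
session_predictions <- function(session) {
  if (length(session$predictions) == 0) {
    stop_ecg("Session has no emitted beats.", class = "ecgbeat_validation_error")
  }
  dplyr::bind_rows(session$predictions)
}

#' Per-beat latency summary of a session
#'
#' Summarises recorded per-beat timings and the fraction of beats whose
#' end-to-end processing finished inside the real-time bound of 0.6 s — the
#' shortest normal inter-beat interval, hence the deadline a streaming
#' classifier must meet to keep pace with the heart.
#'
#' @param session A [stream_session()] with at least one emitted beat.
#' @param threshold_s Real-time bound in seconds.
#' @return One-row tibble with `n_beats`, mean/min/max `inference_s`, mean
#'   `end_to_end_s` and `realtime_fraction` (share of beats under the
#'   bound).
#' @export
latency_report <- function(session, threshold_s = 0.6) {
  preds <- session_predictions(session)
  if (nrow(preds) == 0) {
    stop_ecg("Session has no emitted beats.", class = "ecgbeat_validation_error")
  }
  tibble(n_beats = nrow(preds),
         mean_inference_s = mean(preds$inference_s),
         min_inference_s = min(preds$inference_s),
         max_inference_s = max(preds$inference_s),
         mean_end_to_end_s = mean(preds$end_to_end_s),
         realtime_threshold_s = threshold_s,
         realtime_fraction = mean(preds$end_to_end_s < threshold_s))
}

# ---- HTTP service ---------------------------------------------------------

#' Create a classification web service
#'
#' Holds a model plus any number of isolated streaming sessions; requests
#' are routed by [handle_request()] and can be served over TCP by [serve()].
#'
#' @param model A `beat_classifier`.
#' @param fs_source Source sampling rate for new sessions.
#' @param ... Further arguments passed to [stream_session()].
#' @return An `ecg_service` environment.
#' @export
ecg_service <- function(model, fs_source = 130, ...) {
  srv <- new.env(parent = emptyenv())
  srv$model <- model
  srv$fs_source <- fs_source
  srv$session_args <- list(...)
  srv$sessions <- list()
  srv$next_id <- 1L
  class(srv) <- "ecg_service"
  srv
}

#' Route one HTTP-style request
#'
#' Endpoints: `POST /session` (create a session), `POST /session/{id}/chunk`
#' (ingest a JSON chunk, returns the newly emitted predictions),
#' `GET /session/{id}/stats` (latency summary), `GET /health`.
#'
#' @param service An [ecg_service()].
#' @param method HTTP method string.
#' @param path Request path.
#' @param body Request body text (JSON), if any.
#' @return A list with `status` (integer) and `body` (R list, serialised to
#'   JSON by the transport layer).
#' @export
handle_request <- function(service, method, path, body = NULL) {
  parts <- strsplit(sub("^/", "", path), "/")[[1]]
  if (method == "GET" && identical(parts, "health")) {
    return(list(status = 200L, body = list(status = "ok")))
  }
  if (method == "POST" && identical(parts, "session")) {
    id <- as.character(service$next_id)
    service$next_id <- service$next_id + 1L
    service$sessions[[id]] <- do.call(
      stream_session, c(list(model = service$model,
                             fs_source = service$fs_source),
                        service$session_args))
    return(list(status = 200L, body = list(session_id = id)))
  }
  if (length(parts) == 3 && parts[1] == "session") {
    sess <- service$sessions[[parts[2]]]
    if (is.null(sess)) {
      return(list(status = 404L,
                  body = list(error = sprintf("unknown session id '%s'", parts[2]))))
    }
    if (method == "POST" && parts[3] == "chunk") {
      chunk <- tryCatch(decode_chunk(body), ecgbeat_schema_error = identity)
      if (inherits(chunk, "condition")) {
        return(list(status = 400L, body = list(error = conditionMessage(chunk))))
      }
      preds <- tryCatch(ingest(sess, chunk), ecgbeat_schema_error = identity)
      if (inherits(preds, "condition")) {
        return(list(status = 400L, body = list(error = conditionMessage(preds))))
      }
      return(list(status = 200L, body = list(predictions = prediction_payload(preds))))
    }
    if (method == "GET" && parts[3] == "stats") {
      rep <- tryCatch(latency_report(sess), ecgbeat_validation_error = identity)
      if (inherits(rep, "condition")) {
        return(list(status = 400L, body = list(error = conditionMessage(rep))))
      }
      return(list(status = 200L, body = as.list(rep)))
    }
  }
  list(status = 404L, body = list(error = sprintf("no route for %s %s", method, path)))
}

prediction_payload <- function(preds) {
  lapply(seq_len(nrow(preds)), function(i) {
    list(beat_index = preds$beat_index[i],
         r_peak_time_s = preds$r_peak_time_s[i],
         label = as.character(preds$label[i]),
         confidence = preds$confidence[i],
         inference_ms = 1000 * preds$inference_s[i])
  })
}

#' Serve the classification service over TCP
#'
#' A small single-threaded development server: accepts one connection at a
#' time, parses a minimal HTTP/1.1 request, routes it through
#' [handle_request()], and answers with a JSON body.
#'
#' @param service An [ecg_service()].
#' @param host Bind address.
#' @param port TCP port.
#' @param max_requests Stop after this many requests (`Inf` to run forever);
#'   useful for scripted shutdown.
#' @return Number of requests served, invisibly.
#' @export
serve <- function(service, host = "127.0.0.1", port = 8787L,
                  max_requests = Inf) {
  sock <- serverSocket(port)
  on.exit(close(sock), add = TRUE)
  served <- 0L
  while (served < max_requests) {
    con <- socketAccept(sock, blocking = TRUE, open = "r+b")
    req <- tryCatch(read_http_request(con), error = function(e) NULL)
    if (!is.null(req)) {
      resp <- handle_request(service, req$method, req$path, req$body)
      payload <- as.character(jsonlite::toJSON(resp$body, auto_unbox = TRUE,
                                               digits = NA, null = "null"))
      writeLines(c(sprintf("HTTP/1.1 %d OK", resp$status),
                   "Content-Type: application/json",
                   sprintf("Content-Length: %d", nchar(payload, "bytes")),
                   "Connection: close", "", payload),
                 con, sep = "\r\n")
      flush(con)
    }
    close(con)
    served <- served + 1L
  }
  invisible(served)
}

read_http_request <- function(con) {
  request_line <- readLines(con, n = 1)
  parts <- strsplit(request_line, " ")[[1]]
  headers <- character(0)
  repeat {
    l <- readLines(con, n = 1)
    if (length(l) == 0 || !nzchar(l)) break
    headers <- c(headers, l)
  }
  clen <- grep("^content-length:", headers, ignore.case = TRUE, value = TRUE)
  body <- NULL
  if (length(clen)) {
    nb <- as.integer(trimws(sub(":", "", sub("^[^:]*:", "", clen[1]))))
    if (nb > 0) body <- rawToChar(readBin(con, "raw", n = nb))
  }
  list(method = parts[1], path = parts[2], body = body)
}
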