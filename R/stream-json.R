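# JSON dialect of the client-server streaming loop: the client posts chunks
# of raw ECG samples, the service answers with per-beat predictions.
# Chunk schema:    {"timestamp_ms": int, "fs": number, "samples": [numbers]}
# Response schema: {"beat_index": int, "r_peak_time_s": number,
#                   "label": "N|S|V|F|Q", "confidence": number,
#                   "inference_ms": number}

#' Construct a stream chunk
#'
#' @param timestamp_ms Client-side timestamp in milliseconds.
#' @param fs Sampling rate of the samples, in Hz (constant within a session).
#' @param samples Non-empty numeric vector of ECG samples (mV).
#' @return A list of class `stream_chunk`.
#' @export
stream_chunk <- function(timestamp_ms, fs, samples) {
  check_scalar(fs, "fs")
  if (length(samples) == 0 || !is.numeric(samples)) {
    stop_ecg("`samples` must be a non-empty numeric vector.",
             class = "ecgbeat_schema_error")
  }
  structure(list(timestamp_ms = as.numeric(timestamp_ms), fs = as.numeric(fs),
                 samples = as.numeric(samples)),
            class = "stream_chunk")
}

#' Encode a stream chunk as JSON
#'
#' Numbers are serialised in decimal at full precision, so that
#' `decode_chunk(encode_chunk(x))` reproduces `x` exactly.
#'
#' @param chunk A [stream_chunk()].
#' @return A single JSON string.
#' @export
encode_chunk <- function(chunk) {
  if (!inherits(chunk, "stream_chunk")) {
    stop_ecg("`chunk` must be a stream_chunk.", class = "ecgbeat_schema_error")
  }
  as.character(jsonlite::toJSON(
    list(timestamp_ms = chunk$timestamp_ms, fs = chunk$fs,
         samples = chunk$samples),
    auto_unbox = TRUE, digits = I(17)))
}

#' Decode a JSON stream chunk
#'
#' @param json JSON text following the chunk schema.
#' @return A [stream_chunk()].
#' @export
decode_chunk <- function(json) {
  parsed <- tryCatch(jsonlite::fromJSON(json),
                     error = function(e) {
                       stop_ecg(sprintf("Malformed JSON: %s", conditionMessage(e)),
                                class = "ecgbeat_schema_error")
                     })
  for (key in c("timestamp_ms", "fs", "samples")) {
    if (is.null(parsed[[key]])) {
      stop_ecg(sprintf("Chunk JSON is missing required field \"%s\".", key),
               class = "ecgbeat_schema_error")
    }
  }
  stream_chunk(parsed$timestamp_ms, parsed$fs, parsed$samples)
}
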