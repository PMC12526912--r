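# Minimal WFDB-format support: header parsing, signal formats 16 and 212,
# and the MIT annotation format, enough to read arrhythmia-database records
# and to round-trip the package's own synthetic fixtures. Sample indices are
# exposed 1-based on the R side; the on-disk format is 0-based.

# MIT annotation type codes <-> annotation symbols (beat and the common
# non-beat marks).
mit_code_symbol <- function() {
  c(`1` = "N", `2` = "L", `3` = "R", `4` = "a", `5` = "V", `6` = "F",
    `7` = "J", `8` = "A", `9` = "S", `10` = "E", `11` = "j", `12` = "/",
    `13` = "Q", `14` = "~", `16` = "|", `18` = "s", `19` = "T", `20` = "*",
    `21` = "D", `22` = "\"", `23` = "=", `24` = "p", `25` = "B", `26` = "!",
    `27` = "t", `28` = "+", `29` = "u", `30` = "?", `31` = "[", `32` = "]",
    `33` = "]", `34` = "e", `35` = "n", `37` = "x", `38` = "f", `41` = "r")
}

#' Map MIT-BIH annotation symbols to AAMI classes
#'
#' The fixed five-group mapping: `N, L, R, e, j` to N; `A, a, J, S` to S;
#' `V, E` to V; `F` to F; `/, f, Q` to Q. Any other symbol — including all
#' non-beat annotations such as rhythm changes (`+`) or signal-quality marks
#' — maps to `NA`.
#'
#' @param symbols Character vector of single-character annotation symbols.
#' @return Factor with levels `N, S, V, F, Q`; `NA` for non-beat symbols.
#' @export
map_to_aami <- function(symbols) {
  groups <- list(N = c("N", "L", "R", "e", "j"),
                 S = c("A", "a", "J", "S"),
                 V = c("V", "E"),
                 F = "F",
                 Q = c("/", "f", "Q"))
  lut <- unlist(lapply(names(groups), function(g) {
    stats::setNames(rep(g, length(groups[[g]])), groups[[g]])
  }))
  as_aami_factor(unname(lut[as.character(symbols)]))
}

parse_hea <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  record_id <- sub("/.*$", "", rec[1])
  n_sig <- as.integer(rec[2])
  fs <- if (length(rec) >= 3) as.numeric(sub("/.*$", "", rec[3])) else 250
  n_samples <- if (length(rec) >= 4) as.integer(rec[4]) else NA_integer_
  sig <- lapply(seq_len(n_sig), function(i) {
    f <- strsplit(trimws(lines[1 + i]), "\\s+")[[1]]
    gain_field <- if (length(f) >= 3) f[3] else "200"
    gain_num <- sub("\\(.*", "", sub("/.*$", "", gain_field))
    baseline <- if (grepl("\\(", gain_field)) {
      as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_field))
    } else if (length(f) >= 5) as.numeric(f[5]) else 0
    gain <- as.numeric(gain_num)
    if (!is.finite(gain) || gain == 0) gain <- 200
    list(file = f[1], format = as.integer(sub("x.*|:.*|\\+.*", "", f[2])),
         gain = gain, baseline = baseline,
         description = if (length(f) >= 9) paste(f[9:length(f)], collapse = " ")
                       else sprintf("sig%d", i))
  })
  list(record_id = record_id, n_sig = n_sig, fs = fs, n_samples = n_samples,
       signals = sig)
}

read_dat_16 <- function(path, n_sig, n_samples) {
  raw <- readBin(path, "integer", n = n_sig * n_samples, size = 2,
                 signed = TRUE, endian = "little")
  matrix(raw, ncol = n_sig, byrow = TRUE)
}

read_dat_212 <- function(path, n_sig, n_samples) {
  total <- n_sig * n_samples
  bytes <- readBin(path, "integer", n = ceiling(total / 2) * 3, size = 1,
                   signed = FALSE)
  n_pairs <- length(bytes) %/% 3
  b <- matrix(bytes[seq_len(n_pairs * 3)], nrow = 3)
  s1 <- b[1, ] + bitwShiftL(bitwAnd(b[2, ], 0x0F), 8)
  s2 <- b[3, ] + bitwShiftL(bitwAnd(bitwShiftR(b[2, ], 4), 0x0F), 8)
  tosigned <- function(v) ifelse(v > 2047, v - 4096, v)
  flat <- as.vector(rbind(tosigned(s1), tosigned(s2)))[seq_len(total)]
  matrix(flat, ncol = n_sig, byrow = TRUE)
}

#' Read a WFDB record
#'
#' Reads the header and signal file of a WFDB record (formats 16 and 212)
#' and returns one lead in physical units (mV).
#'
#' @param path Record base path without extension (e.g. `"mitdb/100"`).
#' @param lead Lead index (1-based) or lead description string; defaults to
#'   the first lead.
#' @return An `ecg_record` with `signal` (mV), `fs`, `record_id`.
#' @export
read_wfdb <- function(path, lead = 1L) {
  hea <- paste0(path, ".hea")
  if (!file.exists(hea)) {
    stop_ecg(sprintf("Header file not found: %s", hea), class = "ecgbeat_io_error")
  }
  h <- parse_hea(hea)
  if (is.character(lead)) {
    leads <- vapply(h$signals, function(s) s$description, "")
    li <- match(lead, leads)
    if (is.na(li)) {
      stop_ecg(sprintf("Lead '%s' not present. Available: %s", lead,
                       paste(leads, collapse = ", ")),
               class = "ecgbeat_validation_error")
    }
  } else {
    li <- as.integer(lead)
    if (li < 1 || li > h$n_sig) {
      stop_ecg(sprintf("Lead index %d out of range (record has %d).", li, h$n_sig),
               class = "ecgbeat_validation_error")
    }
  }
  sig <- h$signals[[li]]
  dat <- file.path(dirname(path), sig$file)
  if (!file.exists(dat)) {
    stop_ecg(sprintf("Signal file not found: %s", dat), class = "ecgbeat_io_error")
  }
  n <- h$n_samples
  if (is.na(n)) {
    bytes <- file.size(dat)
    n <- if (sig$format == 212) floor(bytes * 2 / 3 / h$n_sig)
         else floor(bytes / 2 / h$n_sig)
  }
  adc <- switch(as.character(sig$format),
    `16` = read_dat_16(dat, h$n_sig, n),
    `212` = read_dat_212(dat, h$n_sig, n),
    stop_ecg(sprintf("Unsupported WFDB signal format %d.", sig$format),
             class = "ecgbeat_io_error"))
  structure(list(signal = (adc[, li] - sig$baseline) / sig$gain,
                 fs = h$fs, rpeaks = integer(0),
                 labels = as_aami_factor(character(0)),
                 components = NULL, record_id = h$record_id),
            class = "ecg_record")
}

#' Write a record as WFDB files (format 16)
#'
#' Writes `<path>.hea` and `<path>.dat` (16-bit, gain 200 ADC units per mV)
#' and, when the record carries beat annotations, `<path>.atr` in the MIT
#' annotation format. Used for round-trip fixtures.
#'
#' @param record An `ecg_record`; beats in `rpeaks`/`labels` (AAMI classes
#'   are written through their canonical MIT symbols N/A/V/F/Q).
#' @param path Record base path without extension.
#' @return `path`, invisibly.
#' @export
write_wfdb <- function(record, path) {
  gain <- 200
  adc <- as.integer(pmax(pmin(round(record$signal * gain), 32767), -32768))
  dat_name <- paste0(basename(path), ".dat")
  writeLines(c(sprintf("%s 1 %g %d", basename(path), record$fs, length(adc)),
               sprintf("%s 16 %d(0)/mV 16 0 %d 0 0 MLII", dat_name, gain,
                       adc[1])),
             paste0(path, ".hea"))
  writeBin(adc, paste0(path, ".dat"), size = 2, endian = "little")
  if (length(record$rpeaks)) {
    syms <- c(N = "N", S = "A", V = "V", F = "F", Q = "Q")[
      as.character(record$labels)]
    write_wfdb_annotations(record$rpeaks, syms, paste0(path, ".atr"))
  }
  invisible(path)
}

write_wfdb_annotations <- function(samples, symbols, path) {
  lut <- mit_code_symbol()
  codes <- as.integer(names(lut))[match(symbols, lut)]
  if (anyNA(codes)) {
    stop_ecg("Symbol without an MIT annotation code.", class = "ecgbeat_io_error")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  prev <- 0L
  word <- function(code, incr) {
    writeBin(as.integer(c(bitwAnd(incr, 0xFF),
                          bitwOr(bitwShiftL(code, 2),
                                 bitwShiftR(incr, 8)))),
             con, size = 1)
  }
  for (i in seq_along(samples)) {
    t0 <- as.integer(samples[i]) - 1L   # on-disk times are 0-based
    incr <- t0 - prev
    prev <- t0
    if (incr >= 1024L) {
      word(59L, 0L)   # SKIP: 4-byte interval follows, high word first
      hi <- incr %/% 65536L; lo <- incr %% 65536L
      writeBin(as.integer(c(hi %% 256L, hi %/% 256L,
                            lo %% 256L, lo %/% 256L)), con, size = 1)
      word(codes[i], 0L)
    } else {
      word(codes[i], incr)
    }
  }
  writeBin(as.integer(c(0L, 0L)), con, size = 1)  # EOF
  invisible(path)
}

#' Read WFDB annotations
#'
#' Parses a MIT-format annotation file and returns every annotation with its
#' symbol and derived AAMI class (NA for non-beat symbols).
#'
#' @param path Record base path without extension.
#' @param ext Annotation file extension (default `"atr"`).
#' @return A tibble with `sample` (1-based), `symbol`, `aami`.
#' @export
read_wfdb_annotations <- function(path, ext = "atr") {
  file <- paste0(path, ".", ext)
  if (!file.exists(file)) {
    stop_ecg(sprintf("Annotation file not found: %s", file),
             class = "ecgbeat_io_error")
  }
  bytes <- readBin(file, "integer", n = file.size(file), size = 1,
                   signed = FALSE)
  lut <- mit_code_symbol()
  i <- 1L; t0 <- 0L
  samples <- integer(0); symbols <- character(0)
  while (i + 1L <= length(bytes)) {
    b1 <- bytes[i]; b2 <- bytes[i + 1L]; i <- i + 2L
    code <- bitwShiftR(b2, 2)
    incr <- bitwOr(bitwShiftL(bitwAnd(b2, 3L), 8), b1)
    if (code == 0L && incr == 0L) break            # EOF
    if (code == 59L) {                             # SKIP
      if (i + 3L > length(bytes)) break
      hi <- bytes[i] + 256L * bytes[i + 1L]
      lo <- bytes[i + 2L] + 256L * bytes[i + 3L]
      t0 <- t0 + hi * 65536L + lo
      i <- i + 4L
      next
    }
    if (code == 63L) {                             # AUX string
      skip <- incr + incr %% 2L
      i <- i + skip
      next
    }
    if (code %in% c(60L, 61L, 62L)) next           # NUM/SUB/CHN modifiers
    t0 <- t0 + incr
    sym <- lut[as.character(code)]
    samples <- c(samples, t0 + 1L)
    symbols <- c(symbols, if (is.na(sym)) "?" else unname(sym))
  }
  tibble(sample = samples, symbol = symbols, aami = map_to_aami(symbols))
}

#' Load a directory of WFDB records with annotations
#'
#' Reads every record under `root`, applying the standard exclusion of the
#' paced-rhythm records 102, 104, 107 and 217 by default (the full
#' 48-record arrhythmia database then yields 44 records).
#'
#' @param root Directory containing `.hea`/`.dat`(/`.atr`) files.
#' @param exclude Character vector of record ids to drop.
#' @param lead Lead selector passed to [read_wfdb()].
#' @return A tibble with `record_id`, `record` (list of `ecg_record`) and
#'   `annotations` (list of annotation tibbles, `NULL` when absent).
#' @export
load_ecg_dataset <- function(root, exclude = c("102", "104", "107", "217"),
                             lead = 1L) {
  heas <- sort(list.files(root, pattern = "\\.hea$", full.names = TRUE))
  if (length(heas) == 0) {
    stop_ecg(sprintf("No WFDB records found under %s.", root),
             class = "ecgbeat_validation_error")
  }
  ids <- sub("\\.hea$", "", basename(heas))
  keep <- !(ids %in% as.character(exclude))
  rows <- lapply(which(keep), function(k) {
    base <- sub("\\.hea$", "", heas[k])
    ann <- if (file.exists(paste0(base, ".atr"))) {
      read_wfdb_annotations(base)
    } else NULL
    tibble(record_id = ids[k], record = list(read_wfdb(base, lead)),
           annotations = list(ann))
  })
  dplyr::bind_rows(rows)
}
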