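# Minimal European Data Format (EDF) support: classic EDF, 16-bit samples,
# one-second data records. Enough for polysomnography fixtures and round
# trips; EDF+ annotations and vendor dialects are out of scope.

#' Construct a polysomnography recording
#'
#' A `psg_recording` holds a multichannel EEG signal in microvolts together
#' with its sampling rate, channel labels (10-20 names) and the identifier of
#' the recording device (used to look up calibration curves).
#'
#' @param data Numeric matrix, samples x channels, in microvolts.
#' @param fs Sampling rate in samples/second (positive).
#' @param channels Character vector of unique channel labels, one per column.
#' @param subject_id Subject identifier.
#' @param device_id Recording device identifier.
#' @return An object of class `psg_recording`.
#' @export
new_recording <- function(data, fs, channels,
                          subject_id = "unknown", device_id = "unknown") {
  data <- as.matrix(data)
  assert_that(is.numeric(fs) && length(fs) == 1 && fs > 0,
              "`fs` must be a single positive number")
  assert_that(length(channels) == ncol(data),
              "one channel label per data column is required")
  assert_that(!anyDuplicated(channels), "channel labels must be unique")
  colnames(data) <- channels
  structure(
    list(subject_id = subject_id, channels = as.character(channels),
         fs = fs, data = data, device_id = device_id),
    class = "psg_recording"
  )
}

#' @export
print.psg_recording <- function(x, ...) {
  cat(sprintf(
    "<psg_recording> subject %s, device %s: %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
    x$subject_id, x$device_id, length(x$channels), nrow(x$data), x$fs,
    nrow(x$data) / x$fs
  ))
  cat("channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

# ---- low-level header helpers -----------------------------------------------

edf_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  vapply(s, function(si) {
    if (nchar(si) > width) substr(si, 1, width) else si
  }, character(1), USE.NAMES = FALSE)
}

read_ascii <- function(con, n) {
  raw <- readBin(con, "raw", n = n)
  if (length(raw) < n) {
    abort("truncated EDF header", class = "sleepspectra_format_error")
  }
  trimws(rawToChar(raw))
}

#' Read an EDF polysomnography file
#'
#' Reads a classic EDF file and returns the signal in physical units
#' (microvolts for EEG channels). No re-referencing or filtering is applied;
#' the samples are returned exactly as stored, scaled by the file's
#' digital-to-physical calibration.
#'
#' @param path Path to an EDF file.
#' @param channels Optional character vector of channels to load; defaults to
#'   all channels in file order. A missing channel is an error listing the
#'   available labels.
#' @param subject_id,device_id Optional overrides; default to the EDF patient
#'   and recording-id header fields.
#' @return A [new_recording()] object.
#' @export
read_edf <- function(path, channels = NULL, subject_id = NULL,
                     device_id = NULL) {
  assert_that(file.exists(path), sprintf("no such file: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))

  version <- read_ascii(con, 8)
  if (version != "0") {
    abort(sprintf("not a classic EDF file (version field '%s')", version),
          class = "sleepspectra_format_error")
  }
  patient <- read_ascii(con, 80)
  recording_id <- read_ascii(con, 80)
  read_ascii(con, 8)  # start date
  read_ascii(con, 8)  # start time
  header_bytes <- as.integer(read_ascii(con, 8))
  read_ascii(con, 44)
  n_records <- as.integer(read_ascii(con, 8))
  record_dur <- as.numeric(read_ascii(con, 8))
  ns <- as.integer(read_ascii(con, 4))
  if (any(is.na(c(header_bytes, n_records, record_dur, ns))) || ns < 1 ||
      n_records < 0 || record_dur <= 0) {
    abort("malformed EDF header fields", class = "sleepspectra_format_error")
  }

  labels <- vapply(seq_len(ns), function(i) read_ascii(con, 16), character(1))
  vapply(seq_len(ns), function(i) read_ascii(con, 80), character(1)) # transducer
  vapply(seq_len(ns), function(i) read_ascii(con, 8), character(1))  # phys dim
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) read_ascii(con, 8), character(1)))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) read_ascii(con, 8), character(1)))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) read_ascii(con, 8), character(1)))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) read_ascii(con, 8), character(1)))
  vapply(seq_len(ns), function(i) read_ascii(con, 80), character(1)) # prefilter
  spr <- as.integer(vapply(seq_len(ns), function(i) read_ascii(con, 8), character(1)))
  vapply(seq_len(ns), function(i) read_ascii(con, 32), character(1)) # reserved

  if (any(is.na(c(phys_min, phys_max, dig_min, dig_max, spr))) ||
      any(dig_max <= dig_min)) {
    abort("malformed EDF signal headers", class = "sleepspectra_format_error")
  }

  expected <- header_bytes + n_records * sum(spr) * 2
  if (file.size(path) < expected) {
    abort(sprintf(
      "truncated EDF file: %d bytes on disk, %d expected from header",
      file.size(path), expected
    ), class = "sleepspectra_format_error")
  }

  wanted <- channels %||% labels
  missing <- setdiff(wanted, labels)
  if (length(missing) > 0) {
    abort(sprintf(
      "channel(s) %s not in file; available: %s",
      paste(missing, collapse = ", "), paste(labels, collapse = ", ")
    ), class = "sleepspectra_lookup_error")
  }

  # All EEG use cases here have a common sampling rate.
  idx <- match(wanted, labels)
  if (length(unique(spr[idx])) != 1) {
    abort("requested channels have differing sampling rates",
          class = "sleepspectra_format_error")
  }
  fs <- spr[idx[1]] / record_dur

  out <- matrix(0, nrow = n_records * spr[idx[1]], ncol = length(idx))
  offsets <- c(0, cumsum(spr))
  for (rec in seq_len(n_records)) {
    block <- readBin(con, "integer", n = sum(spr), size = 2, endian = "little")
    if (length(block) < sum(spr)) {
      abort("truncated EDF data record", class = "sleepspectra_format_error")
    }
    for (j in seq_along(idx)) {
      s <- idx[j]
      dig <- block[(offsets[s] + 1):offsets[s + 1]]
      rows <- ((rec - 1) * spr[s] + 1):(rec * spr[s])
      out[rows, j] <- (dig - dig_min[s]) *
        (phys_max[s] - phys_min[s]) / (dig_max[s] - dig_min[s]) + phys_min[s]
    }
  }

  new_recording(out, fs = fs, channels = wanted,
                subject_id = subject_id %||% (if (nzchar(patient)) patient else "unknown"),
                device_id = device_id %||% (if (nzchar(recording_id)) recording_id else "unknown"))
}

#' Write a recording to an EDF file
#'
#' Writes classic EDF with one-second data records and 16-bit samples. The
#' physical range is set per channel to the observed signal range, so a
#' write/read round trip is exact up to 16-bit quantization.
#'
#' @param recording A [new_recording()] object whose length is a whole number
#'   of seconds (padded with zeros otherwise, with a warning).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "psg_recording"))
  fs <- recording$fs
  assert_that(abs(fs - round(fs)) < 1e-9,
              "EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  x <- recording$data
  n <- nrow(x)
  if (n %% fs != 0) {
    pad <- fs - n %% fs
    warn(sprintf("padding recording with %d zero samples to fill the last 1 s record", pad))
    x <- rbind(x, matrix(0, pad, ncol(x)))
    n <- nrow(x)
  }
  n_records <- n / fs
  ns <- ncol(x)

  phys_min <- apply(x, 2, min)
  phys_max <- apply(x, 2, max)
  flat <- phys_max - phys_min < 1e-12
  phys_min[flat] <- phys_min[flat] - 1
  phys_max[flat] <- phys_max[flat] + 1
  dig_min <- rep(-32768, ns)
  dig_max <- rep(32767, ns)

  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(x, width) {
    writeBin(charToRaw(paste(edf_field(x, width), collapse = "")), con)
  }
  header_bytes <- 256 + 256 * ns
  put("0", 8)
  put(recording$subject_id, 80)
  put(recording$device_id, 80)
  put("01.01.00", 8)
  put("00.00.00", 8)
  put(header_bytes, 8)
  put("", 44)
  put(n_records, 8)
  put(1, 8)
  put(ns, 4)
  put(recording$channels, 16)
  put(rep("", ns), 80)
  put(rep("uV", ns), 8)
  put(formatC(phys_min, format = "g", digits = 6), 8)
  put(formatC(phys_max, format = "g", digits = 6), 8)
  put(dig_min, 8)
  put(dig_max, 8)
  put(rep("", ns), 80)
  put(rep(fs, ns), 8)
  put(rep("", ns), 32)

  # re-read the header strings we just wrote so the round trip quantizes with
  # the stored (string-truncated) physical range, not the full-precision one
  pmin_s <- as.numeric(formatC(phys_min, format = "g", digits = 6))
  pmax_s <- as.numeric(formatC(phys_max, format = "g", digits = 6))

  for (rec in seq_len(n_records)) {
    rows <- ((rec - 1) * fs + 1):(rec * fs)
    for (s in seq_len(ns)) {
      dig <- round((x[rows, s] - pmin_s[s]) * (dig_max[s] - dig_min[s]) /
                     (pmax_s[s] - pmin_s[s]) + dig_min[s])
      dig <- pmin(pmax(dig, dig_min[s]), dig_max[s])
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
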