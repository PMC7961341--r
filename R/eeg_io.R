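#' Multichannel EEG recording
#'
#' Container for one labeled trial of multichannel EEG: a channels x samples
#' matrix in microvolts plus sampling rate and subject/trial/label metadata.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel_names Character vector, one unique name per row of `data`.
#' @param subject_id,trial_id Identifier strings.
#' @param label Emotion class label (any scalar; kept as character).
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(data, fs, channel_names, subject_id = "S1",
                      trial_id = "T1", label = NA_character_) {
  data <- as.matrix(data)
  if (!is.numeric(data) || !all(is.finite(data)))
    stop("recording data must be finite numeric")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar")
  channel_names <- as.character(channel_names)
  if (length(channel_names) != nrow(data))
    stop("channel_names length must match number of data rows")
  if (anyDuplicated(channel_names))
    stop("duplicated channel names")
  structure(
    list(data = data, fs = as.numeric(fs), channel_names = channel_names,
         subject_id = as.character(subject_id), trial_id = as.character(trial_id),
         label = as.character(label)),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat(sprintf("  subject=%s trial=%s label=%s\n", x$subject_id, x$trial_id, x$label))
  invisible(x)
}

duration.eeg_recording <- function(x) ncol(x$data) / x$fs

# ---------------------------------------------------------------------------
# EDF (European Data Format) reader/writer.  EDF stores a fixed-width ASCII
# header followed by int16 little-endian data records; physical values are
# recovered by the per-signal linear digital->physical calibration.

edf_field <- function(con, n) {
  raw <- readChar(con, n, useBytes = TRUE)
  trimws(raw)
}

#' Read an EDF file
#'
#' Minimal reader for uncompressed EDF: all signals must share one sampling
#' rate. Annotation channels are not supported.
#'
#' @param path Path to an `.edf` file.
#' @return A list with `data` (channels x samples, physical units), `fs`,
#'   `channel_names`, and the raw `patient` / `recording` header fields.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("cannot open file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  version <- edf_field(con, 8L)
  patient <- edf_field(con, 80L)
  rec_field <- edf_field(con, 80L)
  edf_field(con, 8L)  # start date
  edf_field(con, 8L)  # start time
  header_bytes <- as.integer(edf_field(con, 8L))
  edf_field(con, 44L)
  n_records <- as.integer(edf_field(con, 8L))
  rec_dur <- as.numeric(edf_field(con, 8L))
  ns <- as.integer(edf_field(con, 4L))
  if (is.na(ns) || ns < 1L) stop("malformed EDF header: no signals")
  labels <- vapply(seq_len(ns), function(i) edf_field(con, 16L), "")
  for (i in seq_len(ns)) edf_field(con, 80L)  # transducer
  for (i in seq_len(ns)) edf_field(con, 8L)   # physical dimension
  pmin <- vapply(seq_len(ns), function(i) as.numeric(edf_field(con, 8L)), 0)
  pmax <- vapply(seq_len(ns), function(i) as.numeric(edf_field(con, 8L)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(edf_field(con, 8L)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(edf_field(con, 8L)), 0)
  for (i in seq_len(ns)) edf_field(con, 80L)  # prefilter
  spr <- vapply(seq_len(ns), function(i) as.integer(edf_field(con, 8L)), 0L)
  for (i in seq_len(ns)) edf_field(con, 32L)
  if (any(!nzchar(labels))) stop("malformed EDF header: empty signal label")
  if (is.na(rec_dur) || rec_dur <= 0) stop("malformed EDF header: record duration")
  if (length(unique(spr)) != 1L)
    stop("EDF signals with differing sampling rates are not supported")
  seek(con, header_bytes)
  total <- sum(spr) * n_records
  raw <- readBin(con, "integer", n = total, size = 2L, signed = TRUE,
                 endian = "little")
  if (length(raw) < total) stop("truncated EDF data section")
  data <- matrix(0, nrow = ns, ncol = spr[1L] * n_records)
  pos <- 0L
  for (r in seq_len(n_records)) {
    for (sig in seq_len(ns)) {
      seg <- raw[(pos + 1L):(pos + spr[sig])]
      cols <- ((r - 1L) * spr[sig] + 1L):(r * spr[sig])
      data[sig, cols] <- seg
      pos <- pos + spr[sig]
    }
  }
  scale <- (pmax - pmin) / (dmax - dmin)
  data <- (data - dmin) * scale + pmin
  list(data = data, fs = spr[1L] / rec_dur, channel_names = labels,
       patient = patient, recording = rec_field, version = version)
}

pad_field <- function(x, n) {
  x <- as.character(x)
  if (nchar(x, type = "bytes") > n) x <- substr(x, 1L, n)
  formatC(x, width = -n, flag = " ")
}

#' Write an EDF file
#'
#' Companion writer to [read_edf()]; one record per second, int16 quantized
#' with a per-channel symmetric physical range.
#'
#' @param rec An [recording()] object; `fs` must be a positive integer.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires integer fs")
  fs <- as.integer(round(fs))
  n <- ncol(rec$data)
  if (n %% fs != 0L) stop("EDF writer requires a whole number of seconds")
  n_records <- n %/% fs
  ns <- nrow(rec$data)
  pmax <- max(1e-6, max(abs(rec$data)))
  dmax <- 32767
  header <- paste0(
    pad_field("0", 8L), pad_field(rec$subject_id, 80L),
    pad_field(rec$trial_id, 80L),
    pad_field("01.01.00", 8L), pad_field("00.00.00", 8L),
    pad_field(256L + ns * 256L, 8L), pad_field("", 44L),
    pad_field(n_records, 8L), pad_field(1L, 8L), pad_field(ns, 4L))
  sig <- paste0(
    paste(vapply(rec$channel_names, pad_field, "", n = 16L), collapse = ""),
    paste(rep(pad_field("", 80L), ns), collapse = ""),
    paste(rep(pad_field("uV", 8L), ns), collapse = ""),
    paste(rep(pad_field(sprintf("%-.6g", -pmax), 8L), ns), collapse = ""),
    paste(rep(pad_field(sprintf("%-.6g", pmax), 8L), ns), collapse = ""),
    paste(rep(pad_field(-dmax, 8L), ns), collapse = ""),
    paste(rep(pad_field(dmax, 8L), ns), collapse = ""),
    paste(rep(pad_field("", 80L), ns), collapse = ""),
    paste(rep(pad_field(fs, 8L), ns), collapse = ""),
    paste(rep(pad_field("", 32L), ns), collapse = ""))
  dig <- round(rec$data / pmax * dmax)
  dig[dig > dmax] <- dmax
  dig[dig < -dmax] <- -dmax
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(header, sig), con, eos = NULL)
  for (r in seq_len(n_records)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Array-container interchange: <stem>.csv data matrix (channels x samples,
# no header) + <stem>.json metadata sidecar.

#' Write a recording as an array container
#'
#' @param rec An [recording()] object.
#' @param stem Path stem; `<stem>.csv` and `<stem>.json` are written.
#' @return `stem`, invisibly.
#' @export
write_recording <- function(rec, stem) {
  stopifnot(inherits(rec, "eeg_recording"))
  utils::write.table(rec$data, paste0(stem, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(fs = rec$fs, channel_names = rec$channel_names,
               subject_id = rec$subject_id, trial_id = rec$trial_id,
               label = rec$label)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' Load a recording from disk
#'
#' @param path For `format = "edf"` an `.edf` file; for `format = "array"`
#'   the path stem of a [write_recording()] container.
#' @param format `"edf"` or `"array"` (`"auto"` guesses from the extension).
#' @param subject_id,trial_id,label Metadata overrides; for EDF the patient
#'   and recording header fields are used as defaults.
#' @return An [recording()] object.
#' @export
load_recording <- function(path, format = c("auto", "edf", "array"),
                           subject_id = NULL, trial_id = NULL, label = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "array"
  if (format == "edf") {
    e <- read_edf(path)
    recording(e$data, e$fs, e$channel_names,
              subject_id = subject_id %||% if (nzchar(e$patient)) e$patient else basename(path),
              trial_id = trial_id %||% if (nzchar(e$recording)) e$recording else basename(path),
              label = label %||% NA_character_)
  } else {
    csv <- paste0(path, ".csv")
    js <- paste0(path, ".json")
    if (!file.exists(csv) || !file.exists(js))
      stop("array container not found at stem: ", path)
    meta <- jsonlite::read_json(js, simplifyVector = TRUE)
    if (is.null(meta$fs) || is.null(meta$channel_names))
      stop("array container metadata missing fs or channel_names")
    data <- as.matrix(utils::read.table(csv, sep = ",", header = FALSE))
    dimnames(data) <- NULL
    recording(data, meta$fs, meta$channel_names,
              subject_id = subject_id %||% meta$subject_id,
              trial_id = trial_id %||% meta$trial_id,
              label = label %||% meta$label)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------

#' Cut a recording into overlapping windows
#'
#' Windows start at multiples of the hop `window_s * (1 - overlap)` seconds
#' (snapped down to integer sample indices) and trailing partial windows are
#' dropped, so every segment has identical length.
#'
#' @param rec An [recording()].
#' @param window_s Window length in seconds (default 15).
#' @param overlap Fractional overlap in `[0, 1)` (default 0.5).
#' @return List of `eeg_segment` objects (empty if the trial is shorter than
#'   one window).
#' @export
sliding_windows <- function(rec, window_s = 15, overlap = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (window_s <= 0) stop("window_s must be positive")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  n <- ncol(rec$data)
  w <- round(window_s * rec$fs)
  hop_s <- window_s * (1 - overlap)
  out <- list()
  k <- 0L
  repeat {
    start <- floor(k * hop_s * rec$fs + 1e-9)
    if (start + w > n) break
    seg <- structure(
      list(data = rec$data[, (start + 1L):(start + w), drop = FALSE],
           fs = rec$fs, start_time = start / rec$fs,
           subject_id = rec$subject_id, trial_id = rec$trial_id,
           label = rec$label),
      class = "eeg_segment")
    out[[length(out) + 1L]] <- seg
    k <- k + 1L
  }
  out
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment> %d ch x %d samples @ %g Hz, start %.2f s, label=%s\n",
              nrow(x$data), ncol(x$data), x$fs, x$start_time, x$label))
  invisible(x)
}
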