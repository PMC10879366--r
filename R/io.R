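#' Read a multichannel EEG recording
#'
#' Reads a recording from CSV (columns `time_s` plus one column per
#' channel) or from a classic EDF file. Channel labels are matched
#' case-insensitively and renamed to the canonical `Fp1`, `Fp2`, `P3`, `P4`
#' where present; the required channels must all be found.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"` or `"edf"`.
#' @param channels Channels that must be present.
#' @return Recording tibble (`time_s` + channel columns).
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf"),
                           channels = c("Fp1", "Fp2", "P3", "P4")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  rec <- if (format == "edf") read_edf(path) else read_recording_csv(path)
  have <- channel_columns(rec)
  idx <- match(tolower(channels), tolower(have))
  if (anyNA(idx)) {
    stop(sprintf("missing channel(s): %s (available: %s)",
                 paste(channels[is.na(idx)], collapse = ", "),
                 paste(have, collapse = ", ")), call. = FALSE)
  }
  names(rec)[match(have[idx], names(rec))] <- channels
  infer_fs(rec$time_s)  # errors on a non-uniform time grid
  rec
}

read_recording_csv <- function(path) {
  rec <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"time_s" %in% names(rec)) {
    stop("CSV recording must contain a time_s column", call. = FALSE)
  }
  dplyr::relocate(rec, "time_s")
}

#' Write a recording as CSV
#'
#' @param rec Recording tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  readr::write_csv(rec, path, progress = FALSE)
  invisible(path)
}

# ---- classic EDF (16-bit) ------------------------------------------------
# Minimal reader/writer for the European Data Format: fixed-width ASCII
# header (256 bytes + 256 per signal), then 1 s data records of 16-bit
# little-endian integers, linearly mapped between the digital and physical
# ranges declared in the header.

pad_ascii <- function(s, width) {
  s <- as.character(s)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)
}

num_ascii <- function(x, width = 8) {
  for (d in 7:1) {
    s <- formatC(x, format = "g", digits = d)
    if (nchar(s) <= width) return(pad_ascii(s, width))
  }
  stop("cannot represent number in EDF header field", call. = FALSE)
}

#' Write a recording as classic EDF
#'
#' Signals are stored as 16-bit integers linearly mapped onto each
#' channel's physical range (microvolts), in 1 s data records; the trailing
#' partial second, if any, is dropped. Quantization error is bounded by half
#' a digital step, i.e. `diff(range(channel)) / 65535 / 2`.
#'
#' @param rec Recording tibble (`time_s` + channels).
#' @param path Output path.
#' @param patient_id Identifier written to the header.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, patient_id = "X") {
  fs <- infer_fs(rec$time_s)
  if (abs(fs - round(fs)) > 1e-9) {
    stop("EDF writer requires an integer sampling rate", call. = FALSE)
  }
  fs <- as.integer(round(fs))
  chans <- channel_columns(rec)
  ns <- length(chans)
  n_rec <- nrow(rec) %/% fs
  if (n_rec < 1) stop("recording shorter than one EDF data record", call. = FALSE)
  n_keep <- n_rec * fs

  phys_min <- phys_max <- numeric(ns)
  dig <- matrix(0L, n_keep, ns)
  for (j in seq_len(ns)) {
    v <- rec[[chans[j]]][seq_len(n_keep)]
    lo <- min(v); hi <- max(v)
    if (hi <= lo) hi <- lo + 1
    # serialize the physical range first and map with the values as stored,
    # so reading back inverts the mapping exactly
    lo <- as.numeric(trimws(num_ascii(lo))); hi <- as.numeric(trimws(num_ascii(hi)))
    if (hi <= lo) hi <- lo + 1
    phys_min[j] <- lo; phys_max[j] <- hi
    dig[, j] <- as.integer(round((v - lo) / (hi - lo) * 65535 - 32768))
    dig[, j] <- pmax(pmin(dig[, j], 32767L), -32768L)
  }

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_ascii("0", 8), pad_ascii(patient_id, 80), pad_ascii("ordeeg", 80),
    pad_ascii("01.01.00", 8), pad_ascii("00.00.00", 8),
    pad_ascii(256 * (1 + ns), 8), pad_ascii("", 44),
    pad_ascii(n_rec, 8), pad_ascii(1, 8), pad_ascii(ns, 4),
    paste(vapply(chans, pad_ascii, character(1), width = 16), collapse = ""),
    paste(rep(pad_ascii("", 80), ns), collapse = ""),
    paste(rep(pad_ascii("uV", 8), ns), collapse = ""),
    paste(vapply(phys_min, num_ascii, character(1)), collapse = ""),
    paste(vapply(phys_max, num_ascii, character(1)), collapse = ""),
    paste(rep(pad_ascii(-32768, 8), ns), collapse = ""),
    paste(rep(pad_ascii(32767, 8), ns), collapse = ""),
    paste(rep(pad_ascii("", 80), ns), collapse = ""),
    paste(rep(pad_ascii(fs, 8), ns), collapse = ""),
    paste(rep(pad_ascii("", 32), ns), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * fs + 1L):(r * fs)
    for (j in seq_len(ns)) {
      writeBin(dig[rows, j], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read a classic EDF recording
#'
#' @param path EDF file path.
#' @return Recording tibble (`time_s` + channels, sample `i` at
#'   `(i - 1) / fs`).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)   # transducer
  for (i in seq_len(ns)) rd(8)    # physical dimension
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)   # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  data <- matrix(0, n_rec * spr[1], ns)
  for (r in seq_len(n_rec)) {
    for (j in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[j], size = 2L, endian = "little",
                   signed = TRUE)
      data[((r - 1L) * spr[j] + 1L):(r * spr[j]), j] <-
        phys_min[j] + (d - dig_min[j]) / (dig_max[j] - dig_min[j]) *
          (phys_max[j] - phys_min[j])
    }
  }
  fs <- spr[1] / rec_dur
  out <- tibble::as_tibble(as.data.frame(data))
  names(out) <- labels
  dplyr::bind_cols(time_s = (seq_len(nrow(out)) - 1) / fs, out)
}

# ---- events --------------------------------------------------------------

#' Read LoR/RoR event annotations
#'
#' @param path CSV with header `patient_id, lor_s, ror_s`.
#' @return Validated tibble.
#' @export
read_events <- function(path) {
  ev <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("patient_id", "lor_s", "ror_s")
  if (!all(need %in% names(ev))) {
    stop("events file must have columns patient_id, lor_s, ror_s", call. = FALSE)
  }
  validate_events(ev[need])
}

validate_events <- function(ev) {
  dup <- ev$patient_id[duplicated(ev$patient_id)]
  if (length(dup) > 0) {
    stop(sprintf("duplicate patient_id in events: %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  bad <- ev$patient_id[ev$lor_s >= ev$ror_s]
  if (length(bad) > 0) {
    stop(sprintf("lor_s must be < ror_s; violated for patient %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  ev
}

#' Write event annotations as CSV
#'
#' @param events Tibble with `patient_id`, `lor_s`, `ror_s`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  readr::write_csv(validate_events(events), path, progress = FALSE)
  invisible(path)
}
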