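# Minimal EDF (European Data Format) writer/reader: 16-bit samples, one data
# record spanning the whole trial, trial metadata in the recording-id field.
# Covers exactly what the cohort exchange format needs; not a general-purpose
# EDF implementation (no EDF+ annotations, no discontinuous records).

edf_pad <- function(x, n) {
  x <- as.character(x)
  if (nchar(x) > n) x <- substr(x, 1L, n)
  formatC(x, width = -n)  # left-justified, space-padded
}

edf_num <- function(x, n) edf_pad(formatC(x, format = "fg", digits = 6), n)

#' Write a multichannel signal as an EDF file
#'
#' Samples are scaled per channel to the full 16-bit digital range, so the
#' round-trip error is bounded by half a quantization step of the channel's
#' physical range.
#'
#' @param signal `[time, channels]` numeric matrix.
#' @param fs Sampling rate in Hz.
#' @param path Output file path.
#' @param recording_id Free-text recording identifier (up to 80 characters);
#'   the cohort writer stores `label=<k> subject=<id> session=<id>` here.
#' @param channel_names Optional channel labels.
#' @return `path`, invisibly.
#' @export
write_edf <- function(signal, fs, path, recording_id = "", channel_names = NULL) {
  stopifnot(is.matrix(signal), nrow(signal) >= 1L, ncol(signal) >= 1L, fs > 0)
  n <- nrow(signal); nc <- ncol(signal)
  if (is.null(channel_names)) channel_names <- sprintf("EEG%03d", seq_len(nc))
  pmin_ <- apply(signal, 2L, min)
  pmax_ <- apply(signal, 2L, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768L; dmax <- 32767L
  header_bytes <- 256L + 256L * nc
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL, useBytes = TRUE)
  wr(edf_pad("0", 8L))
  wr(edf_pad("synthetic cohort", 80L))
  wr(edf_pad(recording_id, 80L))
  wr(edf_pad("01.01.00", 8L)); wr(edf_pad("00.00.00", 8L))
  wr(edf_pad(header_bytes, 8L))
  wr(edf_pad("", 44L))
  wr(edf_pad(1L, 8L))                       # one data record per trial
  wr(edf_num(n / fs, 8L))                   # record duration in seconds
  wr(edf_pad(nc, 4L))
  for (j in seq_len(nc)) wr(edf_pad(channel_names[j], 16L))
  for (j in seq_len(nc)) wr(edf_pad("", 80L))
  for (j in seq_len(nc)) wr(edf_pad("uV", 8L))
  for (j in seq_len(nc)) wr(edf_num(pmin_[j], 8L))
  for (j in seq_len(nc)) wr(edf_num(pmax_[j], 8L))
  for (j in seq_len(nc)) wr(edf_pad(dmin, 8L))
  for (j in seq_len(nc)) wr(edf_pad(dmax, 8L))
  for (j in seq_len(nc)) wr(edf_pad("", 80L))
  for (j in seq_len(nc)) wr(edf_pad(n, 8L))
  for (j in seq_len(nc)) wr(edf_pad("", 32L))
  for (j in seq_len(nc)) {
    scale <- (pmax_[j] - pmin_[j]) / (dmax - dmin)
    dig <- as.integer(round((signal[, j] - pmin_[j]) / scale) + dmin)
    writeBin(dig, con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' @param path EDF file path.
#' @return List with `signal` (`[time, channels]`), `fs`, `recording_id`,
#'   `channel_names`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  version <- rd(8L)
  rd(80L)                                   # patient id
  recording_id <- rd(80L)
  rd(8L); rd(8L)                            # date, time
  rd(8L)                                    # header bytes
  rd(44L)
  n_rec <- as.integer(rd(8L))
  dur <- as.numeric(rd(8L))
  nc <- as.integer(rd(4L))
  channel_names <- vapply(seq_len(nc), function(i) rd(16L), character(1))
  for (i in seq_len(nc)) rd(80L)
  for (i in seq_len(nc)) rd(8L)             # physical dimension
  pmin_ <- vapply(seq_len(nc), function(i) as.numeric(rd(8L)), numeric(1))
  pmax_ <- vapply(seq_len(nc), function(i) as.numeric(rd(8L)), numeric(1))
  dmin <- vapply(seq_len(nc), function(i) as.numeric(rd(8L)), numeric(1))
  dmax <- vapply(seq_len(nc), function(i) as.numeric(rd(8L)), numeric(1))
  for (i in seq_len(nc)) rd(80L)
  ns <- vapply(seq_len(nc), function(i) as.integer(rd(8L)), integer(1))
  for (i in seq_len(nc)) rd(32L)
  sig <- matrix(0, sum(ns[1L]) * n_rec, nc)
  for (r in seq_len(n_rec)) {
    for (j in seq_len(nc)) {
      dig <- readBin(con, "integer", n = ns[j], size = 2L, endian = "little", signed = TRUE)
      scale <- (pmax_[j] - pmin_[j]) / (dmax[j] - dmin[j])
      rows <- ((r - 1L) * ns[j] + 1L):(r * ns[j])
      sig[rows, j] <- (dig - dmin[j]) * scale + pmin_[j]
    }
  }
  fs <- ns[1L] / dur
  list(signal = sig, fs = fs, recording_id = recording_id,
       channel_names = channel_names)
}
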