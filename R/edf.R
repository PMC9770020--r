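# Minimal European Data Format (EDF, 16-bit) I/O. The format stores an ASCII
# header (256 bytes + 256 per signal) followed by data records of little-endian
# int16 samples, linearly mapped between a physical and a digital range.

pad_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  if (nchar(s) > width) stop("EDF header field does not fit: ", x)
  s
}

# Format a physical-range value so that the 8-char header field parses back
# to exactly the value used for scaling.
fmt_range <- function(x) {
  for (d in 6:1) {
    s <- trimws(formatC(x, format = "g", digits = d))
    if (nchar(s) <= 7) return(s)
  }
  stop("cannot format physical range: ", x)
}

#' Write a recording to an EDF (16-bit) file
#'
#' Samples are quantized to the int16 digital range over a symmetric physical
#' range chosen per channel, so the round-trip error is at most
#' `range / 65536` per sample. The recording is truncated to a whole number of
#' 1-second data records.
#'
#' @param rec an `ieeg_recording` with an integer sampling rate.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  ns <- n_channels(rec)
  n_rec <- floor(ncol(rec$data) / fs)
  if (n_rec < 1) stop("recording shorter than one EDF data record (1 s)")
  data <- rec$data[, seq_len(n_rec * fs), drop = FALSE]

  raw_max <- apply(abs(data), 1, max)
  pmax_str <- vapply(seq_len(ns), function(s) {
    v <- if (raw_max[s] > 0) raw_max[s] * 1.001 else 1
    str <- fmt_range(v)
    while (as.numeric(str) < raw_max[s]) str <- fmt_range(v <- v * 1.1)
    str
  }, "")
  pmax_ <- as.numeric(pmax_str)          # scale with the header's exact value
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field("synthetic", 80),
    pad_field("eventconn export", 80),
    pad_field("01.01.00", 8),
    pad_field("00.00.00", 8),
    pad_field(256 * (ns + 1), 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field(1, 8),
    pad_field(ns, 4)
  )
  sig_hdr <- paste0(
    paste(vapply(rec$channel_labels, pad_field, "", width = 16), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field("uV", 8), ns), collapse = ""),
    paste(vapply(paste0("-", pmax_str), pad_field, "", width = 8),
          collapse = ""),
    paste(vapply(pmax_str, pad_field, "", width = 8), collapse = ""),
    paste(rep(pad_field(dmin, 8), ns), collapse = ""),
    paste(rep(pad_field(dmax, 8), ns), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field(fs, 8), ns), collapse = ""),
    paste(rep(pad_field("", 32), ns), collapse = "")
  )
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL)

  scale <- (dmax - dmin) / (2 * pmax_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    block <- round((data[, idx, drop = FALSE] + pmax_) * scale) + dmin
    block <- pmin(pmax(block, dmin), dmax)
    # record layout: all samples of signal 1, then signal 2, ...
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF (16-bit) file into a recording
#'
#' All signals must share one sampling rate; digital values are mapped back to
#' the physical (uV) range stored in the header.
#'
#' @param path path to an EDF file.
#' @return an `ieeg_recording`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8 + 80 + 80 + 8 + 8)
  as.numeric(rd(8))                      # header bytes (recomputed below)
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("unreadable EDF header")

  field <- function(width) {
    vapply(seq_len(ns), function(i) trimws(rd(width)), "")
  }
  labels <- field(16)
  field(80); field(8)
  pmin_ <- as.numeric(field(8)); pmax_ <- as.numeric(field(8))
  dmin <- as.numeric(field(8)); dmax <- as.numeric(field(8))
  field(80)
  spr <- as.integer(field(8))
  field(32)
  if (length(unique(spr / rec_dur)) != 1L)
    stop("non-uniform sampling rate across EDF channels")
  fs <- spr[1] / rec_dur

  n_tot <- sum(spr) * n_rec
  raw <- readBin(con, "integer", n = n_tot, size = 2, signed = TRUE,
                 endian = "little")
  if (length(raw) < n_tot) stop("truncated EDF data section")
  data <- matrix(0, nrow = ns, ncol = spr[1] * n_rec)
  offs <- c(0, cumsum(spr))
  rec_len <- sum(spr)
  for (s in seq_len(ns)) {
    idx <- as.vector(outer(seq_len(spr[s]) + offs[s], (seq_len(n_rec) - 1) * rec_len, "+"))
    dig <- raw[idx]
    data[s, ] <- (dig - dmin[s]) / (dmax[s] - dmin[s]) *
      (pmax_[s] - pmin_[s]) + pmin_[s]
  }
  recording(data, fs, labels)
}
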