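# Preprocessing: rational resampling to 1 kHz with anti-aliasing, 60 Hz notch,
# and zero-phase FIR band-pass filtering. All filters are linear-phase
# windowed-sinc (Hamming) designs applied with exact group-delay compensation,
# so channels stay mutually aligned — the lag histograms downstream are
# phase-sensitive.

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

# Hamming-window FIR: ~53 dB stopband, transition width ~ 3.3 * fs / n_taps.
fir_order <- function(fs, transition_hz) {
  n <- ceiling(3.3 * fs / transition_hz)
  if (n %% 2 == 1) n <- n + 1      # even order -> odd, symmetric tap count
  n
}

# Apply a linear-phase FIR (odd length, symmetric) with zero net delay.
zero_phase_fir <- function(x, b) {
  d <- (length(b) - 1L) / 2L
  y <- signal::fftfilt(b, c(x, numeric(d)))
  y[(d + 1L):(d + length(x))]
}

apply_fir_recording <- function(rec, b) {
  out <- rec
  for (ch in seq_len(nrow(rec$data)))
    out$data[ch, ] <- zero_phase_fir(rec$data[ch, ], b)
  out
}

#' Resample a recording to 1 kHz
#'
#' Rational-ratio polyphase resampling with an anti-aliasing/anti-imaging
#' low-pass at 0.9 times the smaller of the input and output Nyquist
#' frequencies. A 1 kHz input is returned unchanged.
#'
#' @param rec an `ieeg_recording` whose sampling rate is rationally related
#'   to 1000 Hz (e.g. 200, 500, 2000 Hz).
#' @param target_fs output rate in Hz (default 1000).
#' @return an `ieeg_recording` at `target_fs`.
#' @export
resample_to_1khz <- function(rec, target_fs = 1000) {
  fs <- rec$fs
  if (fs == target_fs) return(rec)
  if (abs(fs - round(fs)) > 1e-9)
    stop("sampling rate ", fs, " is not rationally related to ", target_fs)
  fs <- round(fs)
  g <- gcd_int(fs, as.integer(target_fs))
  L <- target_fs / g                     # upsampling factor
  M <- fs / g                            # downsampling factor
  fs_up <- fs * L
  if (M > 1) {
    # down-sampling: anti-alias at 0.9 x output Nyquist
    fc <- 0.9 * target_fs / 2
    tw <- max(2, 0.2 * fc)
  } else {
    # pure up-sampling: the imaging filter must preserve content up to the
    # input Nyquist, so the -6 dB point sits exactly there
    fc <- fs / 2
    tw <- max(2, 0.1 * fc)
  }
  b <- signal::fir1(fir_order(fs_up, tw), fc / (fs_up / 2), type = "low") * L

  out_n <- floor(ncol(rec$data) * L / M)
  new_data <- matrix(0, nrow = nrow(rec$data), ncol = out_n)
  for (ch in seq_len(nrow(rec$data))) {
    up <- numeric(ncol(rec$data) * L)
    up[seq(1, length(up), by = L)] <- rec$data[ch, ]
    filt <- zero_phase_fir(up, b)
    new_data[ch, ] <- filt[seq(1, by = M, length.out = out_n)]
  }
  recording(new_data, target_fs, rec$channel_labels, rec$start_time)
}

#' Notch out mains interference
#'
#' Zero-phase FIR band-stop of configurable width centered on the mains
#' frequency (default 60 Hz, width 4 Hz).
#'
#' @param rec an `ieeg_recording` at 1 kHz.
#' @param mains_hz mains frequency in Hz (default 60; use 50 where relevant).
#' @param width_hz total stop-band width in Hz (default 4).
#' @return the filtered `ieeg_recording`.
#' @export
notch_mains <- function(rec, mains_hz = 60, width_hz = 4) {
  if (rec$fs != 1000) stop("notch filtering expects a 1 kHz recording")
  nyq <- rec$fs / 2
  edges <- c(mains_hz - width_hz / 2, mains_hz + width_hz / 2) / nyq
  # narrow IIR band-stop applied forward-backward: deep null at the mains
  # frequency, zero phase, and a much shorter transient than an equivalent FIR
  flt <- signal::butter(2, edges, type = "stop")
  out <- rec
  n <- ncol(rec$data)
  np <- min(n - 1, rec$fs)               # 1 s odd-reflection padding
  for (ch in seq_len(nrow(rec$data))) {
    x <- rec$data[ch, ]
    xp <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[n] - x[(n - 1):(n - np)])
    y <- signal::filtfilt(flt, xp)
    out$data[ch, ] <- y[(np + 1):(np + n)]
  }
  out
}

#' @rdname notch_mains
#' @export
notch_60hz <- function(rec) notch_mains(rec, 60, 4)

#' Zero-phase FIR band-pass into an analysis band
#'
#' Windowed-sinc (Hamming) band-pass with transition width
#' `max(2 Hz, 20% of the lower edge)`, applied with group-delay compensation
#' so the output has no phase shift relative to the input.
#'
#' @param rec an `ieeg_recording` at 1 kHz.
#' @param band a [band_spec()] (uses `fmin`/`fmax`), or a numeric length-2
#'   vector of band edges in Hz.
#' @return the band-limited `ieeg_recording`.
#' @export
bandpass <- function(rec, band) {
  if (rec$fs != 1000) stop("band-pass filtering expects a 1 kHz recording")
  edges <- if (inherits(band, "band_spec")) c(band$fmin, band$fmax) else band
  nyq <- rec$fs / 2
  if (edges[1] <= 0 || edges[2] >= nyq || edges[1] >= edges[2])
    stop("band edges must satisfy 0 < fmin < fmax < ", nyq)
  tw <- max(2, 0.2 * edges[1])
  b <- signal::fir1(fir_order(rec$fs, tw), edges / nyq, type = "pass")
  apply_fir_recording(rec, b)
}

# Welch-style mean power of x in [f1, f2] Hz (rectangular segments).
band_power <- function(x, fs, f1, f2, seg_s = 1) {
  seg <- floor(seg_s * fs)
  n_seg <- floor(length(x) / seg)
  if (n_seg < 1) stop("signal too short for band_power")
  freqs <- (seq_len(seg) - 1) * fs / seg
  sel <- freqs >= f1 & freqs <= f2
  p <- 0
  for (k in seq_len(n_seg)) {
    xs <- x[((k - 1) * seg + 1):(k * seg)]
    P <- Mod(stats::fft(xs - mean(xs)))^2 / seg
    p <- p + mean(P[sel])
  }
  p / n_seg
}
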