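# Interictal spike detection by spectral whitening + robust amplitude
# thresholding, and the pairwise spike-coupling rate matrix.

#' Whiten the power spectrum of a signal
#'
#' Divides the amplitude spectrum by its median-smoothed envelope (robust
#' spectral flattening) and inverse-transforms, preserving phase. Sharp
#' broadband transients such as interictal spikes survive whitening while the
#' 1/f background is flattened, which sharpens their relative amplitude.
#'
#' After flattening, the series is band-limited to `limit_hz` (default
#' 150 Hz): interictal spikes carry essentially no energy above that, so
#' discarding the higher whitened noise sharpens their relative amplitude
#' further without touching the flattened 1-100 Hz range.
#'
#' @param x numeric vector, single channel at 1 kHz, length >= 1 s.
#' @param fs sampling rate in Hz (default 1000).
#' @param smooth_hz width of the median smoother in Hz (default 7).
#' @param limit_hz post-whitening low-pass edge in Hz (`NULL` to disable).
#' @return whitened series of the same length (arbitrary units).
#' @export
whiten <- function(x, fs = 1000, smooth_hz = 7, limit_hz = 150) {
  n <- length(x)
  if (n < fs) stop("whitening needs at least 1 s of signal")
  X <- stats::fft(x - mean(x))
  amp <- Mod(X)
  k <- max(3, round(smooth_hz * n / fs))
  if (k %% 2 == 0) k <- k + 1
  half <- floor(n / 2) + 1L
  env_half <- stats::runmed(amp[1:half], k, endrule = "median")
  env <- numeric(n)
  env[1:half] <- env_half
  if (n > half) env[(half + 1):n] <- rev(env_half[2:(n - half + 1)])
  env <- pmax(env, 1e-12 * max(env, 1e-300))
  w <- Re(stats::fft(X / env, inverse = TRUE)) / n
  if (!is.null(limit_hz) && limit_hz < fs / 2) {
    b <- signal::fir1(200, limit_hz / (fs / 2), type = "low")
    w <- zero_phase_fir(w, b)
  }
  w
}

#' Detect interictal spikes on a whitened signal
#'
#' Candidate spikes are strict local maxima of `abs(whitened)` whose robust
#' z-score `(abs(w) - median(w)) / mad(w)` reaches `z_threshold`; candidates
#' are then kept greedily by descending amplitude subject to a refractory
#' period of `min_isi_ms`.
#'
#' @param whitened output of [whiten()].
#' @param z_threshold robust z cutoff (default 6).
#' @param min_isi_ms minimum inter-spike interval in ms (default 50).
#' @param fs sampling rate in Hz (default 1000).
#' @return sorted spike times in ms (possibly empty).
#' @export
detect_spikes <- function(whitened, z_threshold = 6, min_isi_ms = 50,
                          fs = 1000) {
  a <- abs(whitened)
  n <- length(a)
  if (n < 3) return(numeric(0))
  ctr <- stats::median(whitened)
  sc <- stats::mad(whitened)
  if (sc <= 0) return(numeric(0))
  mid <- 2:(n - 1)
  peaks <- mid[a[mid] > a[mid - 1] & a[mid] >= a[mid + 1]]
  z <- (a[peaks] - ctr) / sc
  cand <- peaks[z >= z_threshold]
  if (!length(cand)) return(numeric(0))
  cand <- cand[order(a[cand], decreasing = TRUE)]
  min_gap <- min_isi_ms * fs / 1000
  kept <- integer(0)
  for (p in cand) {
    if (!length(kept) || all(abs(kept - p) >= min_gap)) kept <- c(kept, p)
  }
  sort((kept - 1) * 1000 / fs)
}

#' Spike-coupling rate for one channel pair
#'
#' The sum of the two channels' spike counts divided by the recording
#' duration; events per second by default, per minute on request (both
#' conventions appear in practice).
#'
#' @param train_i,train_j spike-time vectors (ms).
#' @param duration_s recording duration in seconds (> 0).
#' @param per_minute report events/minute instead of events/second.
#' @return coupling rate.
#' @export
spike_coupling_rate <- function(train_i, train_j, duration_s,
                                per_minute = FALSE) {
  if (duration_s <= 0) stop("duration must be positive")
  r <- (length(train_i) + length(train_j)) / duration_s
  if (per_minute) r * 60 else r
}

#' Pairwise spike-coupling rate matrix
#'
#' @param trains named list of spike-time vectors, one per channel.
#' @param duration_s recording duration in seconds.
#' @param per_minute report events/minute instead of events/second.
#' @return a `spike_coupling_matrix`: list with the symmetric rate matrix `r`
#'   (`r_ij = (n_i + n_j) / duration`), per-channel `counts` and `rates`, and
#'   `duration_s`.
#' @export
spike_coupling_matrix <- function(trains, duration_s, per_minute = FALSE) {
  if (duration_s <= 0) stop("duration must be positive")
  n <- vapply(trains, length, 0L)
  labels <- names(trains) %||% paste0("CH", seq_along(trains))
  r <- outer(n, n, "+") / duration_s
  if (per_minute) r <- r * 60
  dimnames(r) <- list(labels, labels)
  structure(
    list(r = r, counts = stats::setNames(n, labels),
         rates = stats::setNames(n / duration_s, labels),
         duration_s = duration_s, per_minute = per_minute),
    class = "spike_coupling_matrix"
  )
}

#' Channels with the top spike rates
#'
#' Returns the channels whose per-channel spike rate reaches the
#' `(100 - percent)`th percentile: the `max(1, round(percent% of Nc))`
#' highest-rate channels, expanded to include ties at the cutoff.
#'
#' @param rates named numeric vector of per-channel spike rates.
#' @param percent top percentage to keep (default 5).
#' @return character vector of channel labels.
#' @export
top_rate_channels <- function(rates, percent = 5) {
  if (!length(rates)) stop("at least one channel is required")
  k <- max(1L, round(percent / 100 * length(rates)))
  cutoff <- sort(rates, decreasing = TRUE)[k]
  names(rates)[rates >= cutoff]
}
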