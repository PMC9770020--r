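# Shared fixtures, all generated in code.

rms <- function(x) sqrt(mean(x^2))

db <- function(out, inp) 20 * log10(rms(out) / rms(inp))

tone <- function(freq, fs, dur_s, amp = 1) {
  amp * sin(2 * pi * freq * (0:(dur_s * fs - 1)) / fs)
}

# Mean connectivity for a single coupled pair at event level (no rendering).
mean_h_pair <- function(rho, sigma_ms, seed, duration_s = 60,
                        band = band_spec(65, 95, 2, 30, name = "high_gamma")) {
  cfg <- synth_config(n_channels = 2, duration_s = duration_s, seed = seed,
                      coupling = data.frame(i = 1, j = 2, rho = rho,
                                            sigma_ms = sigma_ms))
  g <- generate_event_processes(cfg, "high_gamma")
  st <- connectivity_from_trains(g$trains, names(g$trains), duration_s, band)
  mean_connectivity(st)$h[1, 2]
}

# Independent O(n^2) all-pairs lag histogram oracle (double loop via outer).
brute_force_histogram <- function(train_x, train_y, T_ms, w_ms) {
  N <- 2 * T_ms / w_ms
  counts <- integer(N)
  if (length(train_x) && length(train_y)) {
    lags <- as.vector(outer(train_y, train_x, "-"))
    lags <- lags[lags >= -T_ms & lags < T_ms]
    if (length(lags))
      counts <- tabulate(floor((lags + T_ms) / w_ms) + 1, nbins = N)
  }
  counts
}

poisson_train <- function(rate_hz, duration_s) {
  sort(stats::runif(stats::rpois(1, rate_hz * duration_s),
                    0, duration_s * 1000))
}

tiny_metadata <- function(labels, soz = rep(0L, length(labels)),
                          region = rep("M", length(labels)),
                          gray = rep(1L, length(labels)),
                          noise_free = rep(1L, length(labels))) {
  tibble::tibble(
    label = labels,
    x_mm = 4 * seq_along(labels), y_mm = 0, z_mm = 0,
    region = region, soz = soz,
    hemisphere = rep("R", length(labels)),
    gray_matter = gray, noise_free = noise_free
  )
}

quiet_lmer <- function(expr) suppressMessages(suppressWarnings(expr))
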