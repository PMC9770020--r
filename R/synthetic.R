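# Seeded synthetic-data generator: coupled oscillatory event trains (parent
# Poisson processes with per-channel copy probability and timing jitter,
# optionally tied to inter-contact distance by rho = A * exp(-tau * d)),
# rendered as windowed sinusoidal bursts over pink noise with injected
# biphasic interictal-spike transients. Ground truth is returned for
# recovery testing.

#' Configuration for the synthetic recording generator
#'
#' Defaults describe a single linear depth electrode with 4 mm contact
#' spacing, per-band event rates equal to the band mean frequency (events are
#' oscillation cycles), 10 uV pink-noise background, 20 uV three-cycle
#' bursts, and sparse 70 ms biphasic spikes at 8x the noise SD.
#'
#' @param n_channels number of contacts.
#' @param duration_s recording length in seconds.
#' @param fs sampling rate in Hz.
#' @param bands named list of [band_spec()]s.
#' @param event_rates named per-band event rates in Hz; defaults to each
#'   band's mean event frequency `(fmin + fmax) / 2`.
#' @param coupling data frame of explicitly coupled pairs with columns
#'   `i`, `j` (channel indices), `rho` (copy probability in `[0, 1]`) and
#'   `sigma_ms` (per-channel timing jitter SD); `NULL` for none.
#' @param distance_rule optional list `(A, tau, sigma_ms)`: couples every
#'   pair with `rho = A * exp(-tau * d_ij)` from the geometry. Overrides
#'   `coupling`.
#' @param geometry data frame `label, x_mm, y_mm, z_mm`; default a line of
#'   contacts 4 mm apart.
#' @param noise_sd pink-noise SD in uV.
#' @param burst_amplitude,burst_cycles rendered burst peak amplitude (uV) and
#'   cycle count.
#' @param spike_rate_hz interictal spike rate in events/s (scalar or one
#'   value per channel).
#' @param spike_amplitude spike peak amplitude in uV (default 8x noise SD).
#' @param spike_width_ms spike transient width (default 70 ms).
#' @param soz,region,hemisphere per-channel metadata vectors (defaults:
#'   first 3 contacts SOZ; regions M/L/E in blocks; all right hemisphere).
#' @param seed integer seed fixing all randomness.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_channels = 8,
                         duration_s = 120,
                         fs = 1000,
                         bands = default_bands(),
                         event_rates = NULL,
                         coupling = NULL,
                         distance_rule = NULL,
                         geometry = NULL,
                         noise_sd = 10,
                         burst_amplitude = 20,
                         burst_cycles = 3,
                         spike_rate_hz = 0.1,
                         spike_amplitude = 8 * noise_sd,
                         spike_width_ms = 70,
                         soz = NULL,
                         region = NULL,
                         hemisphere = NULL,
                         seed = 1) {
  if (is.null(event_rates))
    event_rates <- vapply(bands, function(b) b$mean_event_rate_hz, 0)
  if (is.null(geometry))
    geometry <- data.frame(
      label = sprintf("D%02d", seq_len(n_channels)),
      x_mm = 4 * (seq_len(n_channels) - 1), y_mm = 0, z_mm = 0)
  stopifnot(nrow(geometry) == n_channels)
  if (is.null(soz)) soz <- as.integer(seq_len(n_channels) <= 3)
  if (is.null(region))
    region <- rep(c("M", "L", "E"),
                  each = ceiling(n_channels / 3))[seq_len(n_channels)]
  if (is.null(hemisphere)) hemisphere <- rep("R", n_channels)
  if (!is.null(coupling))
    stopifnot(all(coupling$rho >= 0 & coupling$rho <= 1),
              all(coupling$sigma_ms >= 0))
  structure(
    list(n_channels = n_channels, duration_s = duration_s, fs = fs,
         bands = bands, event_rates = event_rates,
         coupling = coupling, distance_rule = distance_rule,
         geometry = geometry, noise_sd = noise_sd,
         burst_amplitude = burst_amplitude, burst_cycles = burst_cycles,
         spike_rate_hz = spike_rate_hz, spike_amplitude = spike_amplitude,
         spike_width_ms = spike_width_ms,
         soz = soz, region = region, hemisphere = hemisphere,
         seed = seed),
    class = "synth_config"
  )
}

#' Channel metadata table implied by a synthetic configuration
#' @param cfg a `synth_config`.
#' @return tibble in the channel-metadata layout (all channels gray-matter
#'   and noise-free).
#' @export
synth_metadata <- function(cfg) {
  tibble::tibble(
    label = cfg$geometry$label,
    x_mm = cfg$geometry$x_mm, y_mm = cfg$geometry$y_mm,
    z_mm = cfg$geometry$z_mm,
    region = cfg$region, soz = cfg$soz, hemisphere = cfg$hemisphere,
    gray_matter = 1L, noise_free = 1L
  )
}

# Stage-specific deterministic seeds derived from the config seed.
seed_for <- function(cfg, stage) {
  offs <- c(theta = 11L, low_gamma = 12L, high_gamma = 13L,
            spikes = 21L, noise = 31L)
  s <- (cfg$seed * 97L + offs[[stage]]) %% .Machine$integer.max
  set.seed(as.integer(s))
}

coupling_pairs <- function(cfg) {
  if (!is.null(cfg$distance_rule)) {
    d <- distance_matrix(cfg$geometry)
    nc <- cfg$n_channels
    out <- NULL
    for (i in seq_len(nc - 1)) for (j in (i + 1):nc) {
      rho <- cfg$distance_rule$A * exp(-cfg$distance_rule$tau * d[i, j])
      out <- rbind(out, data.frame(
        i = i, j = j, rho = min(rho, 1),
        sigma_ms = cfg$distance_rule$sigma_ms %||% 0))
    }
    out
  } else cfg$coupling
}

#' Generate per-channel oscillatory event trains with pairwise coupling
#'
#' Each coupled pair owns a parent Poisson process; each of the two channels
#' copies each parent event independently with probability `rho` and adds
#' Gaussian timing jitter of SD `sigma_ms` (so the pairwise lag SD of shared
#' events is `sigma * sqrt(2)`). An independent Poisson background tops each
#' channel up to the band's target rate. With several coupled partners the
#' parent rates are scaled so the background rate stays non-negative.
#'
#' @param cfg a `synth_config`.
#' @param band_name which band's trains to generate (default "high_gamma").
#' @return list with `trains` (sorted ms times per channel) and `truth`
#'   (parent times, per-channel copy masks, and the coupling table).
#' @export
generate_event_processes <- function(cfg, band_name = "high_gamma") {
  seed_for(cfg, band_name)
  lambda <- cfg$event_rates[[band_name]]
  D <- cfg$duration_s
  nc <- cfg$n_channels
  pairs <- coupling_pairs(cfg)
  copied <- vector("list", nc)
  copy_rate <- numeric(nc)
  truth_pairs <- list()
  if (!is.null(pairs) && nrow(pairs)) {
    g <- numeric(nc)
    for (k in seq_len(nrow(pairs))) {
      g[pairs$i[k]] <- g[pairs$i[k]] + pairs$rho[k]
      g[pairs$j[k]] <- g[pairs$j[k]] + pairs$rho[k]
    }
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$i[k]; j <- pairs$j[k]
      lam_p <- lambda / max(1, g[i], g[j])
      n_par <- stats::rpois(1, lam_p * D)
      parent <- sort(stats::runif(n_par, 0, D * 1000))
      keep_i <- stats::runif(n_par) < pairs$rho[k]
      keep_j <- stats::runif(n_par) < pairs$rho[k]
      jit <- function(t) t + stats::rnorm(length(t), 0, pairs$sigma_ms[k])
      copied[[i]] <- c(copied[[i]], jit(parent[keep_i]))
      copied[[j]] <- c(copied[[j]], jit(parent[keep_j]))
      copy_rate[i] <- copy_rate[i] + pairs$rho[k] * lam_p
      copy_rate[j] <- copy_rate[j] + pairs$rho[k] * lam_p
      truth_pairs[[k]] <- list(i = i, j = j, rho = pairs$rho[k],
                               sigma_ms = pairs$sigma_ms[k],
                               parent = parent, keep_i = keep_i,
                               keep_j = keep_j, parent_rate = lam_p)
    }
  }
  trains <- vector("list", nc)
  for (ch in seq_len(nc)) {
    bg_rate <- lambda - copy_rate[ch]
    if (bg_rate < -1e-9)
      stop("infeasible coupling: background rate negative on channel ", ch)
    bg <- sort(stats::runif(stats::rpois(1, max(0, bg_rate) * D), 0, D * 1000))
    tt <- sort(c(copied[[ch]], bg))
    trains[[ch]] <- tt[tt >= 0 & tt < D * 1000]
  }
  names(trains) <- cfg$geometry$label
  list(trains = trains,
       truth = list(pairs = truth_pairs, coupling = pairs,
                    target_rate = lambda))
}

#' Generate per-channel interictal spike trains
#' @param cfg a `synth_config`.
#' @return list of sorted spike times in ms per channel.
#' @export
generate_spike_trains <- function(cfg) {
  seed_for(cfg, "spikes")
  D <- cfg$duration_s
  rate <- rep(cfg$spike_rate_hz, length.out = cfg$n_channels)
  lapply(stats::setNames(seq_len(cfg$n_channels), cfg$geometry$label),
         function(ch) {
           n <- stats::rpois(1, rate[ch] * D)
           t <- sort(stats::runif(n, 0, D * 1000))
           # enforce a plausible minimum separation of 200 ms
           while (length(t) > 1 && any(diff(t) < 200))
             t <- t[c(TRUE, diff(t) >= 200)]
           t
         })
}

# Deterministic pink (1/f power) noise via spectral shaping.
pink_noise <- function(n, sd = 1) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k)                    # symmetric frequency index
  scale <- 1 / sqrt(pmax(f, 1))
  y <- Re(stats::fft(X * scale, inverse = TRUE)) / n
  y * sd / stats::sd(y)
}

burst_kernel <- function(fc, cycles, amplitude, fs) {
  ns <- round(cycles / fc * fs)
  if (ns %% 2 == 0) ns <- ns + 1
  t <- (seq_len(ns) - (ns + 1) / 2) / fs
  w <- 0.5 * (1 + cos(2 * pi * t / (ns / fs)))     # Hann, peak at center
  amplitude * w * cos(2 * pi * fc * t)
}

spike_kernel <- function(width_ms, amplitude, fs) {
  ns <- round(width_ms / 1000 * fs)
  if (ns %% 2 == 0) ns <- ns + 1
  t <- (seq_len(ns) - (ns + 1) / 2) / fs * 1000    # ms, centered
  s1 <- width_ms / 9; s2 <- width_ms / 5
  k <- exp(-t^2 / (2 * s1^2)) - 0.55 * exp(-(t - width_ms / 6)^2 / (2 * s2^2))
  amplitude * k / max(abs(k))
}

add_kernel_at <- function(x, kernel, centers_ms, fs) {
  half <- (length(kernel) - 1) / 2
  n <- length(x)
  for (t in centers_ms) {
    c0 <- round(t / 1000 * fs) + 1
    i0 <- c0 - half; i1 <- c0 + half
    k0 <- max(1, 1 + (1 - i0)); k1 <- length(kernel) - max(0, i1 - n)
    i0 <- max(1, i0); i1 <- min(n, i1)
    if (i0 <= i1) x[i0:i1] <- x[i0:i1] + kernel[k0:k1]
  }
  x
}

#' Render event and spike trains into a multichannel recording
#'
#' Each band event becomes a Hann-windowed sinusoidal burst at the band's
#' center frequency; each spike a biphasic sharp transient; pink noise is
#' added per channel. Output amplitudes are in uV.
#'
#' @param event_trains named list (by band) of per-channel event-time lists,
#'   as from [generate_event_processes()].
#' @param spike_trains per-channel spike-time list (or `NULL`).
#' @param cfg the `synth_config`.
#' @return an `ieeg_recording`.
#' @export
render_recording <- function(event_trains, spike_trains, cfg) {
  n <- round(cfg$duration_s * cfg$fs)
  nc <- cfg$n_channels
  seed_for(cfg, "noise")
  data <- matrix(0, nc, n)
  kernels <- lapply(cfg$bands, function(b)
    burst_kernel((b$fmin + b$fmax) / 2, cfg$burst_cycles,
                 cfg$burst_amplitude, cfg$fs))
  sk <- spike_kernel(cfg$spike_width_ms, cfg$spike_amplitude, cfg$fs)
  for (ch in seq_len(nc)) {
    x <- if (cfg$noise_sd > 0) pink_noise(n, cfg$noise_sd) else numeric(n)
    for (bn in names(event_trains))
      x <- add_kernel_at(x, kernels[[bn]], event_trains[[bn]][[ch]], cfg$fs)
    if (!is.null(spike_trains))
      x <- add_kernel_at(x, sk, spike_trains[[ch]], cfg$fs)
    data[ch, ] <- x
  }
  recording(data, cfg$fs, cfg$geometry$label)
}

#' Simulate one complete synthetic patient recording
#'
#' Generates event trains for every configured band, spike trains, renders
#' the recording, and returns everything with ground truth.
#'
#' @param cfg a `synth_config`.
#' @return list with `recording`, `metadata`, `events` (per band), `spikes`,
#'   `truth` (per band).
#' @export
simulate_recording <- function(cfg) {
  events <- list(); truth <- list()
  for (bn in names(cfg$bands)) {
    g <- generate_event_processes(cfg, bn)
    events[[bn]] <- g$trains
    truth[[bn]] <- g$truth
  }
  spikes <- generate_spike_trains(cfg)
  rec <- render_recording(events, spikes, cfg)
  list(recording = rec, metadata = synth_metadata(cfg),
       events = events, spikes = spikes, truth = truth)
}

#' Simulate a multi-patient synthetic study
#'
#' Seizure-free (SF) patients receive stronger coupling inside the SOZ than
#' outside; not-seizure-free (NSF) patients instead carry elevated coupling
#' in a designated non-SOZ subset, so their inside-vs-outside contrast is
#' small — the epileptic-network structure the analysis is meant to detect.
#'
#' @param n_patients number of patients (outcomes alternate SF/NSF unless
#'   given).
#' @param outcomes optional character vector of "SF"/"NSF" per patient.
#' @param n_channels,duration_s per-patient geometry and length.
#' @param base_A,base_tau baseline distance-decay coupling rule.
#' @param zone_boost extra copy probability on the affected network's pairs.
#' @param seed master seed; patient p uses `seed + 1000 * p`.
#' @param ... further arguments passed to [synth_config()].
#' @return list of per-patient results as from [simulate_recording()], each
#'   with `$patient` and `$outcome`.
#' @export
make_study <- function(n_patients = 2, outcomes = NULL, n_channels = 8,
                       duration_s = 60, base_A = 0.4, base_tau = 0.09,
                       zone_boost = 0.4, seed = 1, ...) {
  if (is.null(outcomes))
    outcomes <- rep(c("SF", "NSF"), length.out = n_patients)
  study <- vector("list", n_patients)
  for (p in seq_len(n_patients)) {
    cfg <- synth_config(n_channels = n_channels, duration_s = duration_s,
                        seed = seed + 1000L * p, ...)
    d <- distance_matrix(cfg$geometry)
    soz_idx <- which(cfg$soz == 1L)
    boosted <- if (outcomes[p] == "SF") soz_idx else
      setdiff(seq_len(n_channels), soz_idx)[seq_len(min(3, n_channels - length(soz_idx)))]
    pairs <- NULL
    for (i in seq_len(n_channels - 1)) for (j in (i + 1):n_channels) {
      rho <- base_A * exp(-base_tau * d[i, j])
      if (i %in% boosted && j %in% boosted) rho <- rho + zone_boost
      pairs <- rbind(pairs, data.frame(i = i, j = j,
                                       rho = min(rho, 0.95), sigma_ms = 0))
    }
    cfg$coupling <- pairs
    sim <- simulate_recording(cfg)
    sim$patient <- sprintf("P%02d", p)
    sim$outcome <- outcomes[p]
    sim$boosted_channels <- cfg$geometry$label[boosted]
    study[[p]] <- sim
  }
  study
}

#' Simulate a channel-pair table with injected group effects
#'
#' Generates the statistics-stage input directly (no signal rendering):
#' per-patient pair records with a random patient intercept, optional
#' inside-SOZ effects by outcome group applied to the gamma bands, optional
#' linear distance and spike-rate effects, and Gaussian residual noise.
#' Used for parameter-recovery and type-I-error testing of the model stage.
#'
#' @param n_patients number of synthetic patients (half SF, half NSF).
#' @param n_channels contacts per patient (`n_soz` of them in the SOZ).
#' @param n_soz SOZ contacts per patient.
#' @param baseline mean connectivity index.
#' @param inside_effect_sf added to inside-SOZ pairs of SF patients.
#' @param inside_effect_nsf added to inside-SOZ pairs of NSF patients.
#' @param patient_sd SD of the random patient intercept.
#' @param resid_sd residual SD per pair record.
#' @param dist_slope linear distance effect (per mm).
#' @param spike_slope linear spike-rate effect (per events/s).
#' @param seed RNG seed.
#' @return a pair-table tibble as produced by [build_pair_table()].
#' @export
simulate_pair_table <- function(n_patients = 20, n_channels = 12, n_soz = 4,
                                baseline = 0.05,
                                inside_effect_sf = 0.02,
                                inside_effect_nsf = 0,
                                patient_sd = 0.01, resid_sd = 0.04,
                                dist_slope = 0, spike_slope = 0,
                                seed = 1) {
  set.seed(seed)
  outcomes <- rep(c("SF", "NSF"), length.out = n_patients)
  out <- vector("list", n_patients)
  for (p in seq_len(n_patients)) {
    labels <- sprintf("P%02dC%02d", p, seq_len(n_channels))
    geom <- data.frame(label = labels,
                       x_mm = stats::runif(n_channels, 0, 40),
                       y_mm = stats::runif(n_channels, 0, 40),
                       z_mm = stats::runif(n_channels, 0, 40))
    d <- distance_matrix(geom)
    soz <- as.integer(seq_len(n_channels) <= n_soz)
    region <- sample(c("M", "L", "E"), n_channels, replace = TRUE)
    srate <- stats::rgamma(n_channels, shape = 2, rate = 10)
    b_p <- stats::rnorm(1, 0, patient_sd)
    eff <- if (outcomes[p] == "SF") inside_effect_sf else inside_effect_nsf
    rows <- NULL
    for (i in seq_len(n_channels - 1)) for (j in (i + 1):n_channels) {
      zone <- zone_pair_label(soz[i], soz[j])
      mu <- baseline + b_p + eff * (zone == "inside") +
        dist_slope * d[i, j] + spike_slope * (srate[i] + srate[j])
      rows <- rbind(rows, data.frame(
        patient = sprintf("P%02d", p),
        channel_i = labels[i], channel_j = labels[j],
        h_theta = pmax(0, baseline + b_p + stats::rnorm(1, 0, resid_sd)),
        h_low_gamma = pmax(0, mu + stats::rnorm(1, 0, resid_sd)),
        h_high_gamma = pmax(0, mu + stats::rnorm(1, 0, resid_sd)),
        spike_rate = srate[i] + srate[j],
        distance_mm = d[i, j],
        zone_pair = zone,
        region_pair = region_pair_label(region[i], region[j]),
        outcome = outcomes[p]))
    }
    out[[p]] <- rows
  }
  tibble::as_tibble(do.call(rbind, out))
}
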