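test_that("resampling preserves 1 kHz input and anti-aliases downsampling", {
  t1 <- tone(40, 1000, 2)
  rec <- recording(matrix(t1, 1), 1000, "a")
  expect_identical(resample_to_1khz(rec), rec)

  t2 <- (0:(4 * 2000 - 1)) / 2000
  rec2k <- recording(rbind(sin(2 * pi * 700 * t2), sin(2 * pi * 100 * t2)),
                     2000, c("hi", "lo"))
  out <- resample_to_1khz(rec2k)
  expect_equal(out$fs, 1000)
  expect_equal(ncol(out$data), 4000)
  # 700 Hz is above the output Nyquist: attenuated >= 40 dB
  expect_lt(db(out$data[1, ], rec2k$data[1, ]), -40)
  # 100 Hz is deep in the pass band: preserved within ~1 dB
  expect_lt(abs(db(out$data[2, ], rec2k$data[2, ])), 1)
})

test_that("upsampling 200 Hz keeps low-frequency content in place", {
  fs0 <- 200
  x <- tone(40, fs0, 10, amp = 100)
  up <- resample_to_1khz(recording(matrix(x, 1), fs0, "a"))
  expect_equal(up$fs, 1000)
  # spectral peak stays at 40 Hz
  n <- ncol(up$data)
  P <- Mod(stats::fft(up$data[1, ]))^2
  freqs <- (seq_len(n) - 1) * 1000 / n
  half <- freqs <= 500
  expect_equal(freqs[half][which.max(P[half])], 40, tolerance = 0.5)
  # count of local maxima per second changes only marginally vs native 1 kHz
  native <- tone(40, 1000, 10, amp = 100)
  n_native <- length(detect_events(native))
  n_up <- length(detect_events(up$data[1, ]))
  expect_lt(abs(n_up - n_native) / n_native, 0.05)
})

test_that("irrational resampling ratio is rejected", {
  rec <- recording(matrix(rnorm(1000), 1), 333.33, "a")
  expect_error(resample_to_1khz(rec), "rationally")
})

test_that("mains notch attenuates 60 Hz but not the flanks", {
  t1 <- (0:9999) / 1000
  rec <- recording(rbind(sin(2 * pi * 60 * t1), sin(2 * pi * 40 * t1),
                         sin(2 * pi * 80 * t1)), 1000, c("a", "b", "c"))
  out <- notch_60hz(rec)
  expect_lt(db(out$data[1, ], rec$data[1, ]), -30)   # >= 30 dB at 60 Hz
  expect_lt(abs(db(out$data[2, ], rec$data[2, ])), 1)
  expect_lt(abs(db(out$data[3, ], rec$data[3, ])), 1)
})

test_that("mains notch leaves broadband power outside 58-62 Hz intact", {
  set.seed(42)
  wn <- rnorm(20000)
  out <- notch_60hz(recording(matrix(wn, 1), 1000, "w"))$data[1, ]
  lo <- eventconn:::band_power(out, 1000, 1, 55) /
    eventconn:::band_power(wn, 1000, 1, 55)
  hi <- eventconn:::band_power(out, 1000, 65, 300) /
    eventconn:::band_power(wn, 1000, 65, 300)
  expect_lt(abs(lo - 1), 0.05)
  expect_lt(abs(hi - 1), 0.05)
})

test_that("band-pass meets pass-band, stop-band and zero-phase contracts", {
  lg <- band_spec(30, 55, 2, 60, name = "low_gamma")
  t1 <- (0:5999) / 1000
  rec <- recording(rbind(sin(2 * pi * 40 * t1), sin(2 * pi * 10 * t1)),
                   1000, c("pass", "stop"))
  out <- bandpass(rec, lg)
  expect_lt(abs(rms(out$data[1, ]) / rms(rec$data[1, ]) - 1), 0.05)
  expect_lt(db(out$data[2, ], rec$data[2, ]), -40)
  # impulse response is time-symmetric (zero phase)
  imp <- numeric(4001); imp[2001] <- 1
  resp <- bandpass(recording(matrix(imp, 1), 1000, "i"), lg)$data[1, ]
  expect_lt(max(abs(resp - rev(resp))), 1e-12)
  # channel count and ordering never change
  expect_identical(out$channel_labels, rec$channel_labels)
  expect_error(bandpass(rec, c(0, 30)), "band edges")
})

test_that("resampling commutes with band-pass filtering on tones", {
  fs0 <- 2000
  t2 <- (0:(6 * fs0 - 1)) / fs0
  x <- sin(2 * pi * 40 * t2) + 0.5 * sin(2 * pi * 75 * t2)
  lg <- band_spec(30, 55, 2, 60)
  via_resample <- bandpass(resample_to_1khz(recording(matrix(x, 1), fs0, "a")), lg)
  native <- bandpass(recording(matrix(x[seq(1, length(x), 2)], 1), 1000, "a"), lg)
  mid <- 1000:5000                    # compare away from edges
  expect_lt(rms(via_resample$data[1, mid] - native$data[1, mid]) /
              rms(native$data[1, mid]), 0.05)
})

test_that("sampling rate has only a small effect on the gamma event-count ratio", {
  lg <- band_spec(30, 55, 2, 60); hg <- band_spec(65, 95, 2, 30)
  ratios_native <- ratios_up <- numeric(12)
  for (k in 1:12) {
    cfg <- synth_config(n_channels = 1, duration_s = 30, seed = 500 + k,
                        soz = 0L, region = "M", hemisphere = "R",
                        spike_rate_hz = 0)
    sim <- simulate_recording(cfg)
    native <- sim$recording
    low <- resample_to_1khz(recording(
      native$data[, seq(1, ncol(native$data), 5), drop = FALSE], 200,
      native$channel_labels))
    count_ratio <- function(r) {
      nlg <- length(detect_events(bandpass(r, lg)$data[1, ]))
      nhg <- length(detect_events(bandpass(r, hg)$data[1, ]))
      nlg / nhg
    }
    ratios_native[k] <- count_ratio(native)
    ratios_up[k] <- count_ratio(low)
  }
  expect_lt(abs(cohens_d(ratios_native, ratios_up)), 0.3)
})

test_that("segment filters implement the interictal selection criteria", {
  ann <- tibble::tibble(
    onset_ms = c(0, 1e5, 2e5, 3e5, 4e5),
    duration_ms = rep(6e5, 5),
    state_label = c("quiet_wakefulness", "sleep", "quiet_wakefulness",
                    "quiet_wakefulness", "quiet_wakefulness"),
    post_implant_h = c(30, 30, 10, 30, 30),
    hours_to_next_seizure = c(12, 12, 12, 2, 12),
    pre_taper = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  kept <- filter_segments(ann)
  expect_equal(kept$onset_ms, 0)
  expect_error(filter_segments(transform(ann, duration_ms = 0)), "positive")
})
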