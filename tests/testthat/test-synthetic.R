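hg <- band_spec(65, 95, 2, 30, name = "high_gamma")

test_that("full copy with no jitter duplicates the parent train exactly", {
  cfg <- synth_config(n_channels = 2, duration_s = 30, seed = 23,
                      coupling = data.frame(i = 1, j = 2, rho = 1,
                                            sigma_ms = 0))
  g <- generate_event_processes(cfg, "high_gamma")
  expect_identical(g$trains[[1]], g$trains[[2]])
  expect_gt(length(g$trains[[1]]), 0)
})

test_that("uncoupled channels give a flat cross-correlogram", {
  cfg <- synth_config(n_channels = 2, duration_s = 120, seed = 24,
                      coupling = data.frame(i = 1, j = 2, rho = 0,
                                            sigma_ms = 0))
  g <- generate_event_processes(cfg, "high_gamma")
  h <- peri_event_histogram(g$trains[[1]], g$trains[[2]], hg)
  gof <- stats::chisq.test(h$counts)
  expect_gt(gof$p.value, 0.001)
})

test_that("realized event rates stay within 3 standard errors of target", {
  for (s in 1:5) {
    cfg <- synth_config(n_channels = 3, duration_s = 60, seed = 100 + s,
                        coupling = data.frame(i = 1, j = 2, rho = 0.5,
                                              sigma_ms = 2))
    g <- generate_event_processes(cfg, "high_gamma")
    target <- cfg$event_rates[["high_gamma"]] * 60
    for (tr in g$trains)
      expect_lt(abs(length(tr) - target), 3 * sqrt(target))
  }
})

test_that("generation is fully deterministic under a fixed seed", {
  cfg <- synth_config(n_channels = 4, duration_s = 10, seed = 77)
  s1 <- simulate_recording(cfg)
  s2 <- simulate_recording(cfg)
  expect_identical(s1$recording$data, s2$recording$data)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$spikes, s2$spikes)
  s3 <- simulate_recording(synth_config(n_channels = 4, duration_s = 10,
                                        seed = 78))
  expect_false(identical(s1$recording$data, s3$recording$data))
})

test_that("a rendered event round-trips through filtering and detection", {
  cfg <- synth_config(n_channels = 1, duration_s = 10, seed = 25,
                      noise_sd = 0, spike_rate_hz = 0,
                      soz = 0L, region = "M", hemisphere = "R")
  ev <- list(high_gamma = list(5000))
  rec <- render_recording(ev, NULL, cfg)
  filt <- bandpass(rec, hg)
  det <- detect_events(filt$data[1, ])
  expect_equal(sum(abs(det - 5000) <= 3), 1)   # exactly one event at the peak
})

test_that("noise-only recordings yield a finite baseline event rate", {
  cfg <- synth_config(n_channels = 1, duration_s = 30, seed = 26,
                      spike_rate_hz = 0, soz = 0L, region = "M",
                      hemisphere = "R",
                      event_rates = c(theta = 0, low_gamma = 0,
                                      high_gamma = 0))
  sim <- simulate_recording(cfg)
  baseline_rate <- length(detect_events(
    bandpass(sim$recording, hg)$data[1, ])) / 30
  expect_true(is.finite(baseline_rate))        # reported, not asserted
})

test_that("injected spikes round-trip through the whitening detector", {
  cfg <- synth_config(n_channels = 2, duration_s = 120, seed = 27,
                      spike_rate_hz = 0.15,
                      event_rates = c(theta = 0, low_gamma = 0,
                                      high_gamma = 0))
  sim <- simulate_recording(cfg)
  for (ch in 1:2) {
    tru <- sim$spikes[[ch]]
    if (!length(tru)) next
    det <- detect_spikes(whiten(sim$recording$data[ch, ]))
    hits <- sum(vapply(tru, function(t) any(abs(det - t) <= 15), TRUE))
    expect_gte(hits / length(tru), 0.9)
  }
})

test_that("empirical copy probabilities follow the configured distance rule", {
  cfg <- synth_config(n_channels = 10, duration_s = 120, seed = 28,
                      distance_rule = list(A = 0.9, tau = 0.09,
                                           sigma_ms = 0))
  g <- generate_event_processes(cfg, "high_gamma")
  d <- distance_matrix(cfg$geometry)
  rho_hat <- vapply(g$truth$pairs, function(p)
    sqrt(sum(p$keep_i & p$keep_j) / max(1, length(p$parent))), 0)
  dp <- vapply(g$truth$pairs, function(p) d[p$i, p$j], 0)
  fit <- fit_decay(rho_hat, dp)
  expect_lt(abs(fit$tau - 0.09) / 0.09, 0.25)
  expect_lt(abs(fit$A - 0.9), 0.15)
})

test_that("pipeline-level h increases with copy probability at zero jitter", {
  hbar <- vapply(c(0, 0.5, 1), function(rho)
    mean(vapply(1:5, function(s) mean_h_pair(rho, 0, 600 + s), 0)), 0)
  expect_true(all(diff(hbar) > 0))
})

test_that("the synthetic study encodes the outcome-dependent network structure", {
  study <- make_study(n_patients = 2, n_channels = 6, duration_s = 60,
                      seed = 29)
  expect_equal(vapply(study, `[[`, "", "outcome"), c("SF", "NSF"))
  sf <- study[[1]]
  # SF patients: boosted coupling confined to the SOZ contacts
  expect_setequal(sf$boosted_channels,
                  sf$metadata$label[sf$metadata$soz == 1])
  nsf <- study[[2]]
  expect_true(all(nsf$metadata$soz[match(nsf$boosted_channels,
                                         nsf$metadata$label)] == 0))
  expect_s3_class(sf$recording, "ieeg_recording")
  expect_equal(duration_s(sf$recording), 60)
})
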