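lg <- band_spec(30, 55, 2, 60, name = "low_gamma")
hg <- band_spec(65, 95, 2, 30, name = "high_gamma")

test_that("histogram design parameters follow from the band edges", {
  expect_equal(lg$T_ms, 34)
  expect_equal(lg$n_bins, 34L)
  expect_equal(lg$min_event_count, 1020)
  expect_equal(lg$mean_event_rate_hz, 42.5)
  expect_equal(lg$min_duration_s, 24)
  expect_true(lg$feasible)

  expect_equal(hg$T_ms, 16)
  expect_equal(hg$n_bins, 16L)
  expect_equal(hg$min_event_count, 480)
  expect_equal(hg$min_duration_s, 6)

  th <- band_spec(4, 8, 2, 300, name = "theta")
  expect_equal(th$T_ms, 250)
  expect_equal(th$n_bins, 250L)
  expect_equal(th$min_event_count, 7500)
  expect_equal(th$min_duration_s, 1250)
  expect_false(th$feasible)          # 1250 s cannot fit one 300 s window

  expect_error(band_spec(30, 55, bin_width_ms = 3, window_length_s = 60),
               "integer bin count")
  expect_error(band_spec(60, 30, 2, 60), "band edges")
})

test_that("event detection uses neighbor-exceedance semantics", {
  expect_length(detect_events(rep(1, 100)), 0)
  expect_equal(detect_events(c(0, 1, 0)), 1)
  expect_length(detect_events(c(0, 1.0, 0.95, 0)), 0)  # only 0.05 above right
  x <- tone(40, 1000, 1, amp = 100)
  ev <- detect_events(x)
  # brute-force strict local maxima oracle
  mid <- 2:(length(x) - 1)
  oracle <- sum(x[mid] > x[mid - 1] & x[mid] > x[mid + 1])
  expect_equal(length(ev), oracle)
  expect_equal(length(ev), 40)
  expect_true(all(diff(ev) > 0))
})

test_that("peri-event histograms place lags in half-open bins over [-T, T)", {
  h0 <- peri_event_histogram(100, 100, lg)
  expect_equal(h0$total_count, 1)
  expect_equal(which(h0$counts == 1), 18)      # bin containing lag 0: [0, 2)

  h1 <- peri_event_histogram(c(100, 200), c(110, 190), lg)
  expect_equal(h1$total_count, 2)
  expect_equal(which(h1$counts == 1), c(13, 23))  # lags -10 and +10

  # boundary membership: -T included, +T excluded
  h2 <- peri_event_histogram(100, c(100 - lg$T_ms, 100 + lg$T_ms), lg)
  expect_equal(h2$total_count, 1)
  expect_equal(which(h2$counts == 1), 1)

  expect_equal(peri_event_histogram(numeric(0), c(1, 2), lg)$total_count, 0)
})

test_that("histogram counts match the all-pairs brute-force oracle", {
  set.seed(101)
  for (k in 1:100) {
    band <- if (k %% 2) lg else hg
    tx <- poisson_train(runif(1, 5, 60), 5)
    ty <- poisson_train(runif(1, 5, 60), 5)
    fast <- peri_event_histogram(tx, ty, band)
    expect_identical(fast$counts,
                     brute_force_histogram(tx, ty, band$T_ms,
                                           band$bin_width_ms))
  }
})

test_that("entropy matches direct summation and its analytic endpoints", {
  single <- c(0, 0, 12, 0)
  expect_equal(shannon_entropy(single), 0)
  expect_equal(shannon_entropy(rep(7, 34)), log(34))
  expect_equal(shannon_entropy(c(3, 1)),
               -(0.75 * log(0.75) + 0.25 * log(0.25)), tolerance = 1e-12)
  set.seed(11)
  for (k in 1:50) {
    counts <- rpois(34, 5)
    counts[1] <- counts[1] + 1                   # never all-zero
    p <- counts[counts > 0] / sum(counts)
    expect_equal(shannon_entropy(counts), -sum(p * log(p)), tolerance = 1e-12)
  }
  expect_error(shannon_entropy(rep(0, 34)), "empty")
})

test_that("the connectivity index maps entropy onto [0, 1]", {
  expect_identical(connectivity_index(0, 34), 1)
  expect_identical(connectivity_index(log(34), 34), 0)
  expect_equal(connectivity_index(shannon_entropy(c(3, 1)), 34),
               (log(34) - 0.5623351) / log(34), tolerance = 1e-6)
  expect_error(connectivity_index(log(34) + 1, 34), "outside")
  expect_error(connectivity_index(0.5, 1), "at least 2")
})

test_that("sparse identical trains give h = 1 in every valid window", {
  # inter-event gaps > 2T: each pair-window histogram has a single busy bin
  times <- seq(50, 60000 - 50, by = 150)
  st <- connectivity_from_trains(list(times, times), c("a", "b"), 60,
                                 band_spec(65, 95, 2, 30,
                                           min_events_per_bin = 10))
  expect_true(all(st$values[, 1, 2] == 1))
  expect_true(all(st$valid[, 1, 2]))
})

test_that("connectivity stacks are symmetric, bounded and offset-invariant", {
  set.seed(21)
  trains <- lapply(1:4, function(i) poisson_train(60, 60))
  st <- connectivity_from_trains(trains, letters[1:4], 60, hg)
  for (m in seq_len(st$n_windows)) {
    slice <- st$values[m, , ]
    expect_identical(slice, t(slice))
    expect_true(all(slice[is.finite(slice)] >= 0 &
                      slice[is.finite(slice)] <= 1))
  }
  # shifting both channels by a constant leaves the histogram and h unchanged
  h1 <- peri_event_histogram(trains[[1]], trains[[2]], hg)
  h2 <- peri_event_histogram(trains[[1]] + 123.4, trains[[2]] + 123.4, hg)
  expect_identical(h1$counts, h2$counts)

  expect_error(connectivity_from_trains(trains, letters[1:4], 10, hg),
               "shorter than one window")
})

test_that("across-window means respect the validity mask", {
  st <- list(values = array(NA_real_, c(2, 2, 2)),
             valid = array(FALSE, c(2, 2, 2)),
             band = band_spec(65, 95, 2, 30), channels = c("a", "b"),
             n_windows = 2)
  class(st) <- "connectivity_stack"
  st$values[, 1, 2] <- st$values[, 2, 1] <- c(0.2, 0.4)
  st$valid[, 1, 2] <- st$valid[, 2, 1] <- c(TRUE, TRUE)
  cm <- mean_connectivity(st)
  expect_equal(cm$h[1, 2], 0.3)
  expect_equal(cm$n_windows_used[1, 2], 2L)

  st$valid[2, 1, 2] <- st$valid[2, 2, 1] <- FALSE   # mask one window
  cm2 <- mean_connectivity(st)
  expect_equal(cm2$h[1, 2], 0.2)
  expect_equal(cm2$n_windows_used[1, 2], 1L)

  st$valid[, 1, 2] <- st$valid[, 2, 1] <- FALSE     # no valid window -> NA
  expect_true(is.na(mean_connectivity(st)$h[1, 2]))
})

test_that("matrix similarity is 100% for equal matrices and ~0 for shuffled", {
  set.seed(31)
  cfg <- synth_config(n_channels = 8, duration_s = 60, seed = 31,
                      distance_rule = list(A = 0.8, tau = 0.05, sigma_ms = 0))
  g <- generate_event_processes(cfg, "high_gamma")
  cm <- mean_connectivity(
    connectivity_from_trains(g$trains, names(g$trains), 60, hg))
  expect_equal(matrix_similarity(cm, cm), 100)

  shuf <- cm
  ut <- upper.tri(shuf$h)
  perm <- sample(sum(ut))
  vals <- shuf$h[ut][perm]
  shuf$h[ut] <- vals
  shuf$h[lower.tri(shuf$h)] <- t(shuf$h)[lower.tri(shuf$h)]
  expect_lt(abs(matrix_similarity(cm, shuf)), 60)

  few <- cm; few$h[upper.tri(few$h)][-(1:2)] <- NA
  expect_error(matrix_similarity(cm, few), "fewer than 3")
})

test_that("two halves of a stationary recording give similar matrices", {
  cfg <- synth_config(n_channels = 8, duration_s = 240, seed = 77,
                      distance_rule = list(A = 0.8, tau = 0.05, sigma_ms = 0))
  g <- generate_event_processes(cfg, "high_gamma")
  half <- 120 * 1000
  first <- lapply(g$trains, function(t) t[t < half])
  second <- lapply(g$trains, function(t) t[t >= half] - half)
  cm1 <- mean_connectivity(
    connectivity_from_trains(first, names(g$trains), 120, hg))
  cm2 <- mean_connectivity(
    connectivity_from_trains(second, names(g$trains), 120, hg))
  expect_gt(matrix_similarity(cm1, cm2), 80)
})
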