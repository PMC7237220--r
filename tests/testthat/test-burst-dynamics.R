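fs <- 256

test_that("band envelope recovers tone amplitudes and rejects out-of-band", {
  t <- seq(0, 10, by = 1 / fs)
  env <- band_envelope(2 * sin(2 * pi * 20 * t), fs)
  edge <- attr(env, "edge")
  interior <- env[(edge + 1):(length(env) - edge)]
  expect_lt(max(abs(interior - 2)) / 2, 0.02)
  # amplitude-modulated carrier: envelope recovers the modulator
  mod <- 1 + 0.5 * sin(2 * pi * 0.3 * t)
  env_am <- band_envelope(mod * sin(2 * pi * 21 * t), fs)
  interior_am <- (edge + 1):(length(env_am) - edge)
  expect_lt(max(abs(env_am[interior_am] - mod[interior_am])), 0.05)
  # 50 Hz line noise is suppressed into the stop band
  env50 <- band_envelope(sin(2 * pi * 50 * t), fs)
  expect_lt(max(env50[(edge + 1):(length(env50) - edge)]), 0.01)
  expect_error(band_envelope(t, fs, band = c(13, 200)), "Nyquist")
})

test_that("rest thresholds are percentiles of the envelope", {
  expect_equal(threshold_from_rest(rep(3.2, 100)), 3.2)
  set.seed(1)
  u <- runif(2e5)
  expect_equal(threshold_from_rest(u, 75), 0.75, tolerance = 0.01)
  expect_equal(threshold_from_rest(u, 50), 0.5, tolerance = 0.01)
  expect_error(threshold_from_rest(numeric(0)), "empty")
})

test_that("detect_bursts merges sub-gap crossings and enforces min duration", {
  expect_identical(nrow(detect_bursts(rep(0.1, 1000), 1000, 0.5)), 0L)
  # boxcar: above 0-100 ms, below 100-130 ms, above 130-250 ms at 1 kHz
  env <- numeric(400)
  env[1:100] <- 1     # 0 to 100 ms
  env[131:250] <- 1   # 130 to 250 ms; 30 ms gap < 50 ms merge gap
  ev <- detect_bursts(env, 1000, 0.5)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$onset_s, 0)
  expect_equal(ev$duration_ms, 250)
  # the same pattern with a 60 ms gap stays two bursts
  env2 <- numeric(400)
  env2[1:100] <- 1
  env2[161:280] <- 1
  ev2 <- detect_bursts(env2, 1000, 0.5)
  expect_identical(nrow(ev2), 2L)
  # a 30 ms blip dies by the one-cycle minimum
  env3 <- numeric(400)
  env3[1:30] <- 1
  expect_identical(nrow(detect_bursts(env3, 1000, 0.5)), 0L)
  # idempotence
  expect_identical(detect_bursts(env, 1000, 0.5), ev)
})

test_that("raising the threshold never increases above-threshold time", {
  set.seed(2)
  env <- abs(onef_noise(5000, fs, 1)) + 0.2
  total_dur <- function(thr) {
    ev <- detect_bursts(env, fs, thr, min_dur_ms = 0, merge_gap_ms = 0)
    if (nrow(ev) == 0) 0 else sum(ev$duration_ms)
  }
  durs <- vapply(quantile(env, c(0.5, 0.7, 0.9)), total_dur, numeric(1))
  expect_true(all(diff(durs) <= 0))
})

test_that("detected bursts match annotations on a noiseless signal", {
  cfg <- burst_signal_config(noise_amplitude = 0, burst_rate_per_s = 0.08,
                             duration_s = 300, band = c(17, 26),
                             burst_taper = "rect", seed = 11)
  bs <- gen_burst_signal(cfg)
  env <- band_envelope(bs$signal, fs, band = c(13, 30))
  ev <- detect_bursts(env, fs, threshold = cfg$burst_amplitude / 2)
  ann <- bs$annotations
  expect_identical(nrow(ev), nrow(ann))
  # half-amplitude crossings of a linear-phase filter sit at the edges up
  # to the envelope smearing of the pass band (within ~20 ms here)
  expect_lt(max(abs(ev$onset_s - ann$onset_s)) * 1000, 20)
  expect_lt(max(abs(ev$duration_ms - ann$duration_ms)), 25)
})

test_that("duration histograms recover exponents and reject degenerate data", {
  set.seed(3)
  d <- rtrunc_powerlaw(10000, 1.5)
  dist <- duration_distribution(d)
  expect_length(dist$bin_edges, 21)
  expect_length(dist$counts, 20)
  expect_equal(dist$bin_edges[c(1, 21)], c(50, 2000))
  expect_false(1L %in% dist$fit_bins)
  expect_equal(dist$tau, 1.5, tolerance = 0.07)
  # doubling every count leaves the slope unchanged
  expect_equal(duration_distribution(c(d, d))$tau, dist$tau, tolerance = 1e-6)
  expect_error(duration_distribution(rep(100, 50)), "insufficient support")
  expect_error(duration_distribution(numeric(0)), "no events")
  # heavier tail (smaller tau) means longer mean duration, matched seeds
  set.seed(4); d_light <- rtrunc_powerlaw(5000, 1.9)
  set.seed(4); d_heavy <- rtrunc_powerlaw(5000, 1.3)
  expect_gt(mean(d_heavy), mean(d_light))
})

test_that("burst-rate time courses bin by onset and duration class", {
  empty <- burst_rate_timecourse(list(NULL, NULL))
  expect_true(all(empty == 0))
  expect_length(empty, 120)
  # one 600 ms burst at t = 8 s in each of 100 trials
  trials <- replicate(100, data.frame(onset_s = 8, duration_ms = 600),
                      simplify = FALSE)
  long <- burst_rate_timecourse(trials, class = "long")
  times <- attr(long, "times")
  expect_equal(long[which(times == 8)], 10)     # 100 onsets / (100 x 0.1 s)
  expect_equal(sum(long), 10)
  brief <- burst_rate_timecourse(trials, class = "brief")
  expect_true(all(brief == 0))
  # 300-500 ms bursts belong to neither class
  mids <- replicate(10, data.frame(onset_s = c(1, 2),
                                   duration_ms = c(400, 800)),
                    simplify = FALSE)
  all_rate <- burst_rate_timecourse(mids, class = "all")
  both <- burst_rate_timecourse(mids, class = "brief") +
    burst_rate_timecourse(mids, class = "long")
  expect_true(all(both <= all_rate + 1e-12))
  # events outside the epoch are dropped and counted
  outside <- list(data.frame(onset_s = c(5, 12), duration_ms = c(100, 100)))
  r <- burst_rate_timecourse(outside)
  expect_identical(attr(r, "n_dropped"), 1L)
})
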