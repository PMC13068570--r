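test_that("sessions are deterministic given the seed", {
  cfg <- synth_config(n_channels = 2, duration_s = 30, seed = 31)
  a <- simulate_session(cfg)
  b <- simulate_session(cfg)
  expect_identical(a$recording$signal, b$recording$signal)
  expect_identical(a$events$times, b$events$times)
  expect_identical(a$atoms, b$atoms)
})

test_that("background spectral slope tracks the 1/f exponent", {
  set.seed(32)
  n <- 60000; fs <- 1000
  white <- betabursts:::one_over_f_noise(n, fs, alpha = 0)
  expect_lt(abs(spectral_slope(white, fs)), 0.1)
  pink <- betabursts:::one_over_f_noise(n, fs, alpha = 1)
  expect_lt(abs(spectral_slope(pink, fs) + 1), 0.15)
  expect_equal(sd(pink), 1, tolerance = 1e-9)
})

test_that("atom counts and occupancy follow the Poisson/sparse laws", {
  cfg <- synth_config(n_channels = 1, duration_s = 600,
                      burst_rate_hz = 0.5,
                      suppression_gain = 1, rebound_gain = 1, seed = 33)
  ses <- simulate_session(cfg, signal = FALSE)
  expected <- 0.5 * 600
  expect_lt(abs(nrow(ses$atoms) - expected), 3 * sqrt(expected))
  mean_dur <- cfg$burst_duration_median_s *
    exp(cfg$burst_duration_sdlog^2 / 2)
  expect_lt(abs(ses$occupancy[1] - 0.5 * mean_dur) / (0.5 * mean_dur),
            0.1)
  # rate 0 is impossible by construction; nearly-zero rate leaves the
  # recording essentially unchanged
  cfg0 <- synth_config(n_channels = 1, duration_s = 30,
                       burst_rate_hz = 1e-9, seed = 34)
  ses0 <- simulate_session(cfg0, signal = FALSE)
  expect_equal(nrow(ses0$atoms), 0L)
})

test_that("injected atoms land where the ground truth says", {
  cfg <- synth_config(n_channels = 1, duration_s = 30, snr = 25,
                      burst_rate_hz = 0.3,
                      suppression_gain = 1, rebound_gain = 1, seed = 35)
  ses <- simulate_session(cfg)
  expect_true(all(is.finite(ses$atoms$amplitude) & ses$atoms$amplitude > 0))
  expect_true(all(ses$atoms$onset_s >= 0))
  expect_true(all(ses$atoms$offset_s <= 30))
  # at snr 25 the wavelet power at each atom's bin and center is
  # comfortably above the 6x-median detection threshold
  p <- detection_params()
  tf <- tf_decompose(ses$recording, p)
  pw <- tf$power[[1]]
  above <- vapply(seq_len(nrow(ses$atoms)), function(k) {
    i <- which.min(abs(p$freqs - ses$atoms$freq_hz[k]))
    col <- round(ses$atoms$center_s[k] * 1000) + 1L
    lo <- tf$edges[i] + 1L; hi <- ncol(pw) - tf$edges[i]
    if (col < lo || col > hi) return(NA)
    pw[i, col] > 6 * median(pw[i, lo:hi])
  }, TRUE)
  expect_gte(mean(above, na.rm = TRUE), 0.9)
})

test_that("touch train hits the target median and honors thinning", {
  cfg <- synth_config(n_channels = 1, duration_s = 3600, seed = 36)
  set.seed(36)
  tt <- gen_touch_train(cfg)
  expect_gt(length(tt), 2000)
  expect_lt(abs(median(diff(tt)) - 0.871) / 0.871, 0.10)

  # g_touch = 0: no touch ever lands inside a burst
  cfg0 <- synth_config(n_channels = 1, duration_s = 300, g_touch = 0,
                       burst_rate_hz = 0.6,
                       suppression_gain = 1, rebound_gain = 1, seed = 37)
  ses0 <- simulate_session(cfg0, signal = FALSE)
  s <- floor(ses0$events$times * cfg0$fs) + 1
  expect_equal(sum(ses0$series[1, s]), 0L)

  # g_touch = 1: in-burst rate matches the overall rate (no thinning)
  cfg1 <- synth_config(n_channels = 1, duration_s = 600, g_touch = 1,
                       burst_rate_hz = 0.6,
                       suppression_gain = 1, rebound_gain = 1, seed = 38)
  ses1 <- simulate_session(cfg1, signal = FALSE)
  r <- intra_burst_touch_rate(ses1$series, ses1$events$times,
                              fs = cfg1$fs)
  rate <- length(ses1$events$times) / 600
  se <- sqrt(r$n_in_burst) / r$total_burst_s
  expect_lt(abs(r$btr - rate), 3 * se)
})

test_that("peri-touch gain shapes the atom rate around events", {
  cfg <- synth_config(n_channels = 1, duration_s = 1200,
                      burst_rate_hz = 0.8,
                      suppression_gain = 0.2, rebound_gain = 1.8,
                      seed = 39)
  ses <- simulate_session(cfg, signal = FALSE)
  ev <- ses$events$times
  centers <- ses$atoms$center_s
  # relative lag of each atom center to the nearest upcoming/past touch
  nearest_next <- sapply(centers, function(t) {
    d <- ev[ev >= t]; if (length(d)) min(d) - t else Inf })
  nearest_prev <- sapply(centers, function(t) {
    d <- ev[ev <= t]; if (length(d)) t - max(d) else Inf })
  # count atoms per second of exposure in each window
  expo_sup <- sum(sapply(ev, function(e) 0.8))   # ~0.8 s before each touch
  n_sup <- sum(nearest_next > 0 & nearest_next <= 0.8)
  n_reb <- sum(nearest_prev >= 0.2 & nearest_prev <= 1.0)
  expo_reb <- length(ev) * 0.8
  rate_sup <- n_sup / expo_sup
  rate_reb <- n_reb / expo_reb
  expect_lt(rate_sup, rate_reb)     # suppression below rebound
  expect_lt(rate_sup, 0.8)          # below the base rate
})

test_that("datasets derive per-participant seeds and jitter from the master", {
  cfg <- synth_config(n_channels = 2, duration_s = 20, seed = 40)
  d1 <- gen_dataset(cfg, 3, jitter_sd = 0)
  d2 <- gen_dataset(cfg, 3, jitter_sd = 0)
  expect_identical(lapply(d1, `[[`, "atoms"), lapply(d2, `[[`, "atoms"))
  # jitter 0: every participant shares the template rates
  for (s in d1) expect_equal(s$config$burst_rate_hz, cfg$burst_rate_hz)
  # participants differ from each other
  expect_false(identical(d1[[1]]$atoms, d1[[2]]$atoms))
  # n = 1 reduces to single-session generation
  d3 <- gen_dataset(cfg, 1)
  expect_length(d3, 1)
  dj <- gen_dataset(cfg, 3, jitter_sd = 0.2)
  rates <- sapply(dj, function(s) s$config$burst_rate_hz[1])
  expect_gt(length(unique(rates)), 1)
})
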