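test_that("Morlet power of a stationary sinusoid is a flat ridge at its frequency", {
  fs <- 500
  tt <- seq(0, 20, by = 1 / fs)
  rec <- bb_recording(sin(2 * pi * 20 * tt), fs = fs)
  tf <- tf_decompose(rec, detection_params())
  pw <- tf$power[[1]]
  hw <- max(tf$edges)
  inner <- (hw + 1):(ncol(pw) - hw)
  prof <- rowMeans(pw[, inner])
  expect_equal(tf$freqs[which.max(prof)], 20)
  ridge <- pw[which.max(prof), inner]
  expect_lt(sd(ridge) / mean(ridge), 0.05)
})

test_that("Morlet power scales quadratically and vanishes on zero input", {
  fs <- 500
  x <- rnorm(4 * fs)
  p <- detection_params()
  tf1 <- tf_decompose(bb_recording(x, fs), p)
  tf2 <- tf_decompose(bb_recording(2 * x, fs), p)
  expect_equal(tf2$power[[1]], 4 * tf1$power[[1]], tolerance = 1e-10)
  tf0 <- tf_decompose(bb_recording(rep(0, 4 * fs), fs), p)
  expect_equal(max(tf0$power[[1]]), 0)
})

test_that("tf_decompose rejects Nyquist violations and too-short input", {
  expect_error(tf_decompose(bb_recording(rnorm(100), fs = 50)), "Nyquist")
  expect_error(tf_decompose(bb_recording(rnorm(100), fs = 1000)),
               "shorter than the widest wavelet")
})

test_that("threshold and duration rules reproduce the single-frequency toy cases", {
  # power 1 everywhere except an elevated run; median 1, threshold 6
  base <- rep(1, 1000)
  p20 <- params_for(20)
  short <- base; short[401:460] <- 50        # 60 ms < 2 cycles at 20 Hz
  tf <- make_tfr(list(matrix(short, 1)), freqs = 20, fs = 1000)
  m <- detect_bursts(tf, p20)
  expect_equal(sum(m$series), 0L)

  long <- base; long[401:520] <- 50          # 120 ms >= 100 ms
  tf2 <- make_tfr(list(matrix(long, 1)), freqs = 20, fs = 1000)
  m2 <- detect_bursts(tf2, p20)
  expect_equal(which(m2$series[1, ]), 401:520)
  seg <- extract_segments(m2, tf2)
  expect_equal(seg$duration_s, 0.120)
  expect_equal(seg$peak_freq, 20)

  # a run of exactly 2 cycles survives (rule is "less than 2 cycles")
  exact <- base; exact[401:500] <- 50
  m3 <- detect_bursts(make_tfr(list(matrix(exact, 1)), 20, 1000), p20)
  expect_equal(sum(m3$series), 100L)

  # stationary power never exceeds 6x its own median
  m4 <- detect_bursts(make_tfr(list(matrix(base, 1)), 20, 1000), p20)
  expect_equal(sum(m4$series), 0L)
})

test_that("bursts confined to one channel leave the other channel silent", {
  base <- matrix(1, 2, 2000)
  pow1 <- base[1, ]; pow1[501:800] <- 30
  tf <- make_tfr(list(matrix(pow1, 1), matrix(base[2, ], 1)),
                 freqs = 20, fs = 1000)
  m <- detect_bursts(tf, params_for(20))
  expect_gt(sum(m$series[1, ]), 0)
  expect_equal(sum(m$series[2, ]), 0L)
})

test_that("any-frequency collapse merges overlapping runs into one segment", {
  n <- 1000
  p15 <- rep(1, n); p15[1:200] <- 40      # [0, 200) ms at 15 Hz
  p25 <- rep(1, n); p25[151:300] <- 40    # [150, 300) ms at 25 Hz
  tf <- make_tfr(list(rbind(p15, p25)), freqs = c(15, 25), fs = 1000)
  m <- detect_bursts(tf, params_for(c(15, 25)))
  seg <- extract_segments(m, tf)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$onset_s, 0)
  expect_equal(seg$offset_s, 0.3)

  # segment run-length cases: two separated runs, and the empty series
  s1 <- rep(1, n); s1[101:220] <- 40; s1[501:800] <- 40
  tf2 <- make_tfr(list(matrix(s1, 1)), 20, 1000)
  seg2 <- extract_segments(detect_bursts(tf2, params_for(20)), tf2)
  expect_equal(seg2$duration_s, c(0.120, 0.300))
  tf3 <- make_tfr(list(matrix(1, 1, n)), 15, 1000)
  expect_equal(nrow(extract_segments(detect_bursts(tf3, params_for(15)))),
               0L)
})

test_that("detector matches the per-sample reference on random TF matrices", {
  set.seed(7)
  for (rep in 1:12) {
    nf <- sample(2:5, 1); n <- sample(300:1200, 1)
    freqs <- sort(sample(13:30, nf))
    fs <- sample(c(250, 500, 1000), 1)
    pow <- matrix(rexp(nf * n), nf, n)
    # sprinkle elevated blocks so some runs survive
    for (k in 1:5) {
      i <- sample(nf, 1); a <- sample(n - 150, 1)
      pow[i, a:(a + sample(30:150, 1))] <- rexp(1, rate = 1 / 50)
    }
    edges <- sample(0:20, nf, replace = TRUE)
    tf <- make_tfr(list(pow), freqs, fs, edges)
    got <- detect_bursts(tf, params_for(freqs))
    ref <- ref_detect_channel(pow, freqs, fs, 6, 2, edges)
    expect_identical(tf_mask_matrix(got, 1), ref$tf_mask)
    expect_identical(unname(got$series[1, ]), ref$series)
  }
})

test_that("raising thresholds or minimum cycles never adds detections", {
  set.seed(11)
  pow <- matrix(rexp(3 * 800), 3, 800)
  pow[2, 100:400] <- 30
  tf <- make_tfr(list(pow), freqs = c(15, 20, 25), fs = 1000)
  m6 <- detect_bursts(tf, params_for(c(15, 20, 25), threshold_factor = 6))
  m9 <- detect_bursts(tf, params_for(c(15, 20, 25), threshold_factor = 9))
  expect_true(all(tf_mask_matrix(m6, 1) | !tf_mask_matrix(m9, 1)))
  mc3 <- detect_bursts(tf, params_for(c(15, 20, 25), min_cycles = 3))
  expect_true(all(tf_mask_matrix(m6, 1) | !tf_mask_matrix(mc3, 1)))
})

test_that("the burst mask is invariant to per-channel signal scaling", {
  fs <- 500
  set.seed(3)
  cfg <- synth_config(n_channels = 1, fs = fs, duration_s = 60,
                      snr = 20, seed = 3)
  ses <- simulate_session(cfg)
  rec <- ses$recording
  p <- detection_params()
  m1 <- detect_bursts(tf_decompose(rec, p), p)
  rec$signal <- rec$signal * 37.5
  m2 <- detect_bursts(tf_decompose(rec, p), p)
  expect_identical(m1$series, m2$series)
  expect_identical(m1$tf_runs, m2$tf_runs)
})

test_that("clearly suprathreshold atoms are recovered; sub-2-cycle atoms are not", {
  set.seed(5)
  cfg <- synth_config(n_channels = 2, fs = 1000, duration_s = 120,
                      burst_rate_hz = 0.4, snr = 20,
                      burst_duration_median_s = 0.25,
                      burst_duration_sdlog = 0.2,
                      suppression_gain = 1, rebound_gain = 1, seed = 5)
  ses <- simulate_session(cfg)
  fit <- beta_bursts(ses$recording, mask_inactive = FALSE)
  overlap_any <- vapply(seq_len(nrow(ses$atoms)), function(k) {
    seg <- fit$segments[fit$segments$channel == ses$atoms$channel[k], ]
    any(pmin(seg$offset_s, ses$atoms$offset_s[k]) >
          pmax(seg$onset_s, ses$atoms$onset_s[k]))
  }, TRUE)
  expect_gte(mean(overlap_any), 0.9)

  # atoms shorter than 2 cycles exceed the threshold only over a
  # sub-2-cycle stretch, so the duration rule removes (nearly) all of
  # them at their own frequency bin even though their peak is
  # suprathreshold; occasional noise-assisted survivors are tolerated
  # up to a small fraction
  set.seed(6)
  bg <- gen_background(synth_config(n_channels = 1, fs = 1000,
                                    duration_s = 60, seed = 6))
  short_atoms <- data.frame(
    channel = "ch1", center_s = seq(5, 55, by = 5),
    onset_s = seq(5, 55, by = 5) - 0.04,
    offset_s = seq(5, 55, by = 5) + 0.04,   # 80 ms < 2 cycles at 20 Hz
    duration_s = 0.08, freq_hz = 20, phase = 0, truncated = FALSE)
  cfg2 <- synth_config(n_channels = 1, fs = 1000, duration_s = 60,
                       snr = 8, seed = 6)
  inj <- inject_bursts(bg, cfg2, short_atoms)
  p <- detection_params()
  m <- detect_bursts(tf_decompose(inj$recording, p), p)
  runs <- m$tf_runs[[1]]
  hits <- 0L
  if (!is.null(runs) && nrow(runs)) {
    runs20 <- runs[runs$freq_idx == which(p$freqs == 20), , drop = FALSE]
    for (k in seq_len(nrow(short_atoms))) {
      a <- short_atoms$onset_s[k] * 1000; b <- short_atoms$offset_s[k] * 1000
      hits <- hits + any(runs20$start <= b & runs20$end >= a)
    }
  }
  expect_lte(hits / nrow(short_atoms), 0.25)
})
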