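#' Configuration for the synthetic session generator
#'
#' Describes a ground-truth-annotated synthetic session: 1/f Gaussian
#' background EEG, Hann-windowed sinusoidal burst atoms with Poisson
#' timing, and a lognormal-renewal touch train. Burst-behavior coupling
#' is generated by two separable mechanisms: a peri-touch gain on the
#' burst rate (suppression before, rebound after each touch), and
#' optional thinning of touches that fall inside a burst.
#'
#' Default timing constants mirror self-paced smartphone behavior:
#' inter-touch intervals are lognormal with median 0.871 s and sdlog
#' 0.977 (chosen so the interquartile range is 1.236 s); burst durations
#' are lognormal with median 0.2 s; the default burst rate of 0.5 Hz
#' gives an occupancy near 0.10.
#'
#' @param n_channels number of channels.
#' @param fs sampling rate in Hz.
#' @param duration_s session length in seconds.
#' @param background_alpha 1/f^alpha exponent of the background.
#' @param burst_rate_hz mean burst rate per channel (scalar or
#'   per-channel vector), bursts per second.
#' @param burst_duration_median_s,burst_duration_sdlog lognormal burst
#'   duration parameters.
#' @param burst_freq_range length-2 Hz range from which atom frequencies
#'   are drawn uniformly.
#' @param snr atom peak wavelet power divided by the background median
#'   wavelet power at the atom's frequency; the atom amplitude is
#'   calibrated (compensating the Hann x Morlet smearing) so its
#'   realized time-frequency peak hits this target in the noiseless
#'   limit.
#' @param touch_median_s,touch_sdlog lognormal inter-touch interval
#'   parameters.
#' @param suppression_gain,suppression_window,rebound_gain,rebound_window
#'   peri-touch gain on the burst rate: the rate is multiplied by
#'   `suppression_gain` when the atom center falls within
#'   `suppression_window` (seconds, relative to the nearest upcoming
#'   touch for negative lags) and by `rebound_gain` within
#'   `rebound_window` after a touch. Gains of 1 disable the mechanism.
#' @param coupled_channels integer indices of channels whose burst rate
#'   is modulated (default: all).
#' @param g_touch in-burst touch hazard gain: a candidate touch landing
#'   while the reference channel's burst series is ON is kept with
#'   probability `g_touch` (1 = no thinning, 0 = full suppression).
#' @param touch_ref_channel channel whose series drives touch thinning.
#' @param wavelet_cycles Morlet width used for amplitude calibration
#'   (keep equal to the detector's).
#' @param seed integer seed; mandatory, all session randomness flows
#'   from it.
#' @return An object of class `bb_synth_config`.
#' @export
synth_config <- function(n_channels = 8, fs = 1000, duration_s = 600,
                         background_alpha = 1,
                         burst_rate_hz = 0.5,
                         burst_duration_median_s = 0.2,
                         burst_duration_sdlog = 0.3,
                         burst_freq_range = c(13, 30),
                         snr = 8,
                         touch_median_s = 0.871,
                         touch_sdlog = 0.977,
                         suppression_gain = 0.3,
                         suppression_window = c(-0.8, 0),
                         rebound_gain = 1.5,
                         rebound_window = c(0.2, 1),
                         coupled_channels = seq_len(n_channels),
                         g_touch = 1,
                         touch_ref_channel = 1,
                         wavelet_cycles = 7,
                         seed) {
  if (missing(seed)) stop("`seed` is mandatory in synth_config()")
  stopifnot(n_channels >= 1, fs > 0, duration_s > 0,
            all(burst_rate_hz > 0), burst_duration_median_s > 0,
            touch_median_s > 0, snr > 0,
            g_touch >= 0, g_touch <= 1,
            suppression_gain >= 0, rebound_gain >= 0)
  rate <- rep(burst_rate_hz, length.out = n_channels)
  structure(list(
    n_channels = n_channels, fs = fs, duration_s = duration_s,
    background_alpha = background_alpha, burst_rate_hz = rate,
    burst_duration_median_s = burst_duration_median_s,
    burst_duration_sdlog = burst_duration_sdlog,
    burst_freq_range = burst_freq_range, snr = snr,
    touch_median_s = touch_median_s, touch_sdlog = touch_sdlog,
    suppression_gain = suppression_gain,
    suppression_window = suppression_window,
    rebound_gain = rebound_gain, rebound_window = rebound_window,
    coupled_channels = coupled_channels, g_touch = g_touch,
    touch_ref_channel = touch_ref_channel,
    wavelet_cycles = wavelet_cycles, seed = as.integer(seed)),
    class = "bb_synth_config")
}

#' 1/f^alpha Gaussian background recording
#'
#' Spectrally shaped white noise: the FFT of a white Gaussian series is
#' multiplied by f^(-alpha/2) and inverted; each channel is then
#' RMS-normalized to unit standard deviation. Uses the current RNG
#' stream (call [set.seed()] or use [simulate_session()] for
#' reproducibility).
#'
#' @param cfg a [synth_config()].
#' @return A [bb_recording()].
#' @export
gen_background <- function(cfg) {
  n <- round(cfg$duration_s * cfg$fs)
  sig <- matrix(0, cfg$n_channels, n)
  for (c in seq_len(cfg$n_channels)) {
    sig[c, ] <- one_over_f_noise(n, cfg$fs, cfg$background_alpha)
  }
  bb_recording(sig, fs = cfg$fs,
               labels = paste0("ch", seq_len(cfg$n_channels)))
}

one_over_f_noise <- function(n, fs, alpha) {
  wn <- stats::rnorm(n)
  if (alpha == 0) return(wn / stats::sd(wn))
  W <- stats::fft(wn)
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k) * fs / n            # two-sided frequency axis
  shape <- ifelse(f > 0, f^(-alpha / 2), 0)
  x <- Re(stats::fft(W * shape, inverse = TRUE) / n)
  x / stats::sd(x)
}

# peri-touch rate gain at times tt given touch times ev: multiplicative
# combination of the suppression window (relative to the next touch)
# and the rebound window (relative to the previous touch)
peri_touch_gain <- function(tt, ev, cfg) {
  if (!length(ev)) return(rep(1, length(tt)))
  g <- rep(1, length(tt))
  j <- findInterval(tt, ev)               # ev[j] <= t < ev[j+1]
  t_prev <- ifelse(j >= 1L, tt - ev[pmax(j, 1L)], Inf)
  t_next <- ifelse(j < length(ev), tt - ev[pmin(j + 1L, length(ev))], Inf)
  sup <- t_next >= cfg$suppression_window[1L] &
    t_next <= cfg$suppression_window[2L] & is.finite(t_next)
  reb <- t_prev >= cfg$rebound_window[1L] &
    t_prev <= cfg$rebound_window[2L] & is.finite(t_prev)
  g[sup] <- g[sup] * cfg$suppression_gain
  g[reb] <- g[reb] * cfg$rebound_gain
  g
}

# draw atom centers for one channel: Poisson thinning of a homogeneous
# process at the maximal rate
draw_atoms <- function(cfg, channel, touches) {
  rate <- cfg$burst_rate_hz[channel]
  coupled <- channel %in% cfg$coupled_channels &&
    (cfg$suppression_gain != 1 || cfg$rebound_gain != 1)
  gmax <- if (coupled) max(1, cfg$suppression_gain, cfg$rebound_gain) else 1
  n_cand <- stats::rpois(1L, rate * gmax * cfg$duration_s)
  centers <- sort(stats::runif(n_cand, 0, cfg$duration_s))
  if (coupled && length(centers)) {
    g <- peri_touch_gain(centers, touches, cfg)
    centers <- centers[stats::runif(length(centers)) < g / gmax]
  }
  n <- length(centers)
  dur <- stats::rlnorm(n, log(cfg$burst_duration_median_s),
                       cfg$burst_duration_sdlog)
  freq <- stats::runif(n, cfg$burst_freq_range[1L], cfg$burst_freq_range[2L])
  phase <- stats::runif(n, 0, 2 * pi)
  onset <- centers - dur / 2
  offset <- centers + dur / 2
  truncated <- onset < 0 | offset > cfg$duration_s
  onset <- pmax(onset, 0)
  offset <- pmin(offset, cfg$duration_s)
  keep <- offset > onset
  data.frame(channel = rep(paste0("ch", channel), n), center_s = centers,
             onset_s = onset, offset_s = offset,
             duration_s = offset - onset, freq_hz = freq,
             phase = phase, truncated = truncated)[keep, , drop = FALSE]
}

# binary ground-truth series from an atom table
atoms_to_series <- function(atoms, n_channels, fs, n) {
  series <- matrix(FALSE, n_channels, n,
                   dimnames = list(paste0("ch", seq_len(n_channels)), NULL))
  for (k in seq_len(nrow(atoms))) {
    c <- match(atoms$channel[k], rownames(series))
    a <- floor(atoms$onset_s[k] * fs + 1e-9) + 1L
    b <- min(n, ceiling(atoms$offset_s[k] * fs - 1e-9))
    if (b >= a) series[c, a:b] <- TRUE
  }
  series
}

#' Generate a touch train, optionally thinned during bursts
#'
#' Renewal process with lognormal inter-touch intervals. If
#' `burst_series` is supplied and `cfg$g_touch < 1`, a candidate touch
#' falling on an ON sample of the series is kept with probability
#' `g_touch` (in-burst touch suppression). Uses the current RNG stream.
#'
#' @param cfg a [synth_config()].
#' @param burst_series optional logical vector (one channel's ON/OFF
#'   series at `cfg$fs`).
#' @return Numeric vector of touch times in `[0, duration_s]`.
#' @export
gen_touch_train <- function(cfg, burst_series = NULL) {
  mu <- log(cfg$touch_median_s)
  # draw enough intervals to cover the session, then trim
  n_guess <- ceiling(cfg$duration_s / cfg$touch_median_s * 2) + 50L
  tt <- cumsum(stats::rlnorm(n_guess, mu, cfg$touch_sdlog))
  while (tt[length(tt)] < cfg$duration_s) {
    tt <- c(tt, tt[length(tt)] +
              cumsum(stats::rlnorm(n_guess, mu, cfg$touch_sdlog)))
  }
  tt <- tt[tt < cfg$duration_s]
  if (!is.null(burst_series) && cfg$g_touch < 1 && length(tt)) {
    s <- floor(tt * cfg$fs + 1e-9) + 1L
    s <- pmin(s, length(burst_series))
    on <- burst_series[s]
    u <- stats::runif(length(tt))
    tt <- tt[!on | u < cfg$g_touch]
  }
  tt
}

#' Inject calibrated burst atoms into a recording
#'
#' Adds Hann-windowed sinusoidal atoms at the times, durations, and
#' frequencies given in `atoms`. Amplitudes are calibrated per atom so
#' that the atom's peak Morlet wavelet power at its frequency equals
#' `cfg$snr` times the channel's background median wavelet power at that
#' frequency (estimated from `recording` over the calibration window).
#'
#' @param recording background [bb_recording()].
#' @param cfg a [synth_config()].
#' @param atoms atom table as produced by [simulate_session()]; if
#'   missing, atoms are drawn from the current RNG stream with
#'   `touches = numeric(0)` (no rate modulation).
#' @return List: `recording` (with atoms added), `atoms` (with an
#'   `amplitude` column).
#' @export
inject_bursts <- function(recording, cfg, atoms = NULL) {
  stopifnot(inherits(recording, "bb_recording"))
  n <- ncol(recording$signal)
  if (is.null(atoms)) {
    atoms <- do.call(rbind, lapply(seq_len(cfg$n_channels), function(c)
      draw_atoms(cfg, c, numeric(0))))
  }
  if (!nrow(atoms)) return(list(recording = recording, atoms = atoms))
  med <- background_median_power(recording, cfg)
  atoms$amplitude <- NA_real_
  fs <- recording$fs
  for (k in seq_len(nrow(atoms))) {
    c <- match(atoms$channel[k], recording$labels)
    f <- atoms$freq_hz[k]
    D <- atoms$offset_s[k] - atoms$onset_s[k]
    m <- stats::approx(med$freqs, med$median[c, ], xout = f, rule = 2)$y
    pf <- hann_smear_factor(D, f, cfg$wavelet_cycles)
    A <- sqrt(cfg$snr * m) / (0.5 * pf)
    atoms$amplitude[k] <- A
    a <- floor(atoms$onset_s[k] * fs + 1e-9) + 1L
    b <- min(n, ceiling(atoms$offset_s[k] * fs - 1e-9))
    if (b < a) next
    tau <- ((a:b) - 1L) / fs - atoms$onset_s[k]
    env <- 0.5 * (1 - cos(2 * pi * tau / D))
    recording$signal[c, a:b] <- recording$signal[c, a:b] +
      A * env * sin(2 * pi * f * tau + atoms$phase[k])
  }
  list(recording = recording, atoms = atoms)
}

# peak attenuation of a Hann amplitude envelope of width D under the
# Gaussian temporal smoothing of a `cycles`-cycle Morlet at frequency f:
# (hann * gaussian)(0) with the gaussian a unit-mass density
hann_smear_factor <- function(D, f, cycles) {
  sig_t <- cycles / (2 * pi * f)
  lim <- max(4 * sig_t, D / 2)
  tt <- seq(-lim, lim, length.out = 2001L)
  h <- ifelse(abs(tt) <= D / 2, 0.5 * (1 + cos(2 * pi * tt / D)), 0)
  min(1, sum(h * stats::dnorm(tt, 0, sig_t)) * (tt[2L] - tt[1L]))
}

# per-channel median Morlet power of a recording over the calibration
# window (first <= 60 s), on the detection frequency grid
background_median_power <- function(recording, cfg) {
  fs <- recording$fs
  freqs <- seq(cfg$burst_freq_range[1L], cfg$burst_freq_range[2L])
  n_cal <- min(ncol(recording$signal), round(60 * fs))
  plan <- morlet_plan(freqs, fs, cfg$wavelet_cycles, n_cal)
  med <- matrix(NA_real_, nrow(recording$signal), length(freqs))
  for (c in seq_len(nrow(recording$signal))) {
    pw <- morlet_power_channel(recording$signal[c, seq_len(n_cal)],
                               plan$wl, plan$nf_pad)
    for (i in seq_along(freqs)) {
      lo <- plan$edges[i] + 1L
      hi <- n_cal - plan$edges[i]
      med[c, i] <- stats::median(pw[i, lo:hi])
    }
  }
  list(freqs = freqs, median = med)
}

#' Simulate one ground-truth-annotated session
#'
#' Draws, in order and from a single RNG stream seeded by `cfg$seed`:
#' the touch train, per-channel burst atoms (rate-modulated around
#' touches on coupled channels), optional in-burst touch thinning, and
#' finally (when `signal = TRUE`) the background EEG with calibrated
#' atoms injected.
#'
#' @param cfg a [synth_config()].
#' @param signal generate the waveform-level recording (`TRUE`) or only
#'   the ground-truth binary series, atoms, and events (`FALSE`, much
#'   faster; sufficient for testing everything downstream of detection).
#' @return List of class `bb_synth_session`: `recording` (or `NULL`),
#'   `events` ([bb_events()]), `atoms` (ground-truth table), `series`
#'   (ground-truth logical channels x samples matrix), `occupancy`
#'   (per-channel true occupancy), `config`.
#' @export
simulate_session <- function(cfg, signal = TRUE) {
  stopifnot(inherits(cfg, "bb_synth_config"))
  set.seed(cfg$seed)
  n <- round(cfg$duration_s * cfg$fs)
  touches <- gen_touch_train(cfg)
  atoms <- do.call(rbind, lapply(seq_len(cfg$n_channels), function(c)
    draw_atoms(cfg, c, touches)))
  series <- atoms_to_series(atoms, cfg$n_channels, cfg$fs, n)
  if (cfg$g_touch < 1) {
    ref <- series[cfg$touch_ref_channel, ]
    s <- floor(touches * cfg$fs + 1e-9) + 1L
    on <- ref[pmin(s, n)]
    u <- stats::runif(length(touches))
    touches <- touches[!on | u < cfg$g_touch]
  }
  recording <- NULL
  if (signal) {
    recording <- gen_background(cfg)
    inj <- inject_bursts(recording, cfg, atoms)
    recording <- inj$recording
    atoms <- inj$atoms
  }
  structure(list(recording = recording, events = bb_events(touches),
                 atoms = atoms, series = series,
                 occupancy = rowMeans(series), config = cfg),
            class = "bb_synth_session")
}

#' @export
print.bb_synth_session <- function(x, ...) {
  cat(sprintf("<bb_synth_session> %d channels, %.0f s, %d atoms, %d touches%s\n",
              x$config$n_channels, x$config$duration_s, nrow(x$atoms),
              length(x$events$times),
              if (is.null(x$recording)) " (series only)" else ""))
  invisible(x)
}

#' Simulate a multi-participant dataset
#'
#' Participant seeds are drawn deterministically from the master seed
#' (one `sample.int` stream), and participant-level variability is
#' introduced as lognormal jitter on the burst rate and on the coupling
#' gains.
#'
#' @param cfg template [synth_config()]; its `seed` is the master seed.
#' @param n_participants number of participants.
#' @param jitter_sd SD of the lognormal jitter applied to
#'   `burst_rate_hz` and (on the log scale) to the coupling gains
#'   (0 = identical configs).
#' @param signal passed to [simulate_session()].
#' @return List of `bb_synth_session` objects.
#' @export
gen_dataset <- function(cfg, n_participants, jitter_sd = 0,
                        signal = FALSE) {
  stopifnot(inherits(cfg, "bb_synth_config"), n_participants >= 1)
  set.seed(cfg$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_participants)
  jit <- matrix(stats::rnorm(3L * n_participants, 0, jitter_sd),
                n_participants, 3L)
  lapply(seq_len(n_participants), function(i) {
    ci <- cfg
    ci$seed <- seeds[i]
    ci$burst_rate_hz <- cfg$burst_rate_hz * exp(jit[i, 1L])
    ci$suppression_gain <- min(1, cfg$suppression_gain * exp(jit[i, 2L]))
    ci$rebound_gain <- max(1, cfg$rebound_gain * exp(jit[i, 3L]))
    simulate_session(ci, signal = signal)
  })
}
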