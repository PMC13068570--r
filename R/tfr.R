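#' Burst detection parameters
#'
#' Parameters of the beta-burst detector: the analysis band and grid, the
#' median-multiple power threshold, the minimum duration in cycles, and
#' the Morlet wavelet width.
#'
#' @param f_lo,f_hi band edges in Hz (defaults 13 and 30, the beta band).
#' @param f_step frequency grid step in Hz (default 1, giving 18 bins).
#' @param threshold_factor power threshold as a multiple of the
#'   per-channel, per-frequency median power over the whole valid
#'   recording (default 6). Suprathreshold means strictly greater.
#' @param min_cycles minimum burst duration in cycles at each frequency
#'   (default 2): a suprathreshold run at frequency f must last at least
#'   `min_cycles / f` seconds to survive.
#' @param wavelet_cycles Morlet wavelet width in cycles (default 7); the
#'   Gaussian envelope SD is `wavelet_cycles / (2 * pi * f)` seconds.
#' @return An object of class `bb_params`.
#' @export
detection_params <- function(f_lo = 13, f_hi = 30, f_step = 1,
                             threshold_factor = 6, min_cycles = 2,
                             wavelet_cycles = 7) {
  stopifnot(f_lo < f_hi, f_step > 0, threshold_factor > 0,
            min_cycles >= 1, wavelet_cycles > 0)
  structure(list(f_lo = f_lo, f_hi = f_hi, f_step = f_step,
                 threshold_factor = threshold_factor,
                 min_cycles = min_cycles,
                 wavelet_cycles = wavelet_cycles,
                 freqs = seq(f_lo, f_hi, by = f_step)),
            class = "bb_params")
}

#' @export
print.bb_params <- function(x, ...) {
  cat(sprintf(paste0("<bb_params> %g-%g Hz (step %g), threshold %gx median, ",
                     "min %g cycles, %g-cycle Morlet\n"),
              x$f_lo, x$f_hi, x$f_step, x$threshold_factor, x$min_cycles,
              x$wavelet_cycles))
  invisible(x)
}

# complex Morlet wavelet, amplitude-normalized so that the analytic
# response to a unit-amplitude sinusoid at f has envelope ~ 1/2 times the
# Gaussian frequency response (the natural convolutional convention; the
# detector is invariant to this scale).
morlet_wavelet <- function(f, fs, cycles) {
  sig_t <- cycles / (2 * pi * f)
  hw <- ceiling(3 * sig_t * fs)
  tt <- (-hw:hw) / fs
  w <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sig_t^2))
  w / sum(Mod(w))
}

# half-length (samples) of the wavelet at f: samples closer than this to
# either recording edge are inside the wavelet support and flagged invalid
morlet_halfwidth <- function(f, fs, cycles) {
  as.integer(ceiling(3 * (cycles / (2 * pi * f)) * fs))
}

# FFT convolution of one channel with precomputed wavelet spectra.
# wl_fft: list of list(W = fft of zero-padded wavelet, hw = halfwidth)
# returns nf x n power matrix
morlet_power_channel <- function(x, wl_fft, nf_pad) {
  n <- length(x)
  X <- stats::fft(c(x, numeric(nf_pad - n)))
  out <- matrix(0, length(wl_fft), n)
  for (i in seq_along(wl_fft)) {
    conv <- stats::fft(X * wl_fft[[i]]$W, inverse = TRUE) / nf_pad
    hw <- wl_fft[[i]]$hw
    out[i, ] <- Mod(conv[(hw + 1L):(hw + n)])^2
  }
  out
}

# precompute per-frequency wavelet FFTs for a given signal length
morlet_plan <- function(freqs, fs, cycles, n) {
  hw_max <- morlet_halfwidth(min(freqs), fs, cycles)
  nf_pad <- stats::nextn(n + 2L * hw_max + 1L, 2L)
  plan <- lapply(freqs, function(f) {
    w <- morlet_wavelet(f, fs, cycles)
    hw <- (length(w) - 1L) %/% 2L
    list(W = stats::fft(c(w, numeric(nf_pad - length(w)))), hw = hw)
  })
  list(wl = plan, nf_pad = nf_pad,
       edges = vapply(plan, function(p) p$hw, 1L))
}

#' Morlet wavelet time-frequency power
#'
#' Decomposes each channel into instantaneous power on the detection
#' frequency grid using complex Morlet wavelets (FFT convolution).
#' Samples within half a wavelet length of either recording end are
#' flagged invalid per frequency and excluded from the detection median
#' and from burst detection.
#'
#' @param recording a [bb_recording()].
#' @param params a [detection_params()].
#' @return An object of class `bb_tfr`: list with `power` (list, one
#'   frequencies x samples matrix per channel), `freqs`, `fs`, `edges`
#'   (per-frequency invalid half-width in samples), `labels`, `t0`, and
#'   `seams` (inherited masked-clock seams, if set on the recording).
#' @export
tf_decompose <- function(recording, params = detection_params()) {
  stopifnot(inherits(recording, "bb_recording"),
            inherits(params, "bb_params"))
  fs <- recording$fs
  if (fs < 2 * params$f_hi)
    stop("sampling rate ", fs, " Hz violates Nyquist for f_hi = ",
         params$f_hi, " Hz")
  n <- ncol(recording$signal)
  hw_max <- morlet_halfwidth(params$f_lo, fs, params$wavelet_cycles)
  if (n <= 2L * hw_max + 1L)
    stop("recording (", n, " samples) is shorter than the widest wavelet (",
         2L * hw_max + 1L, " samples)")
  plan <- morlet_plan(params$freqs, fs, params$wavelet_cycles, n)
  power <- lapply(seq_len(nrow(recording$signal)), function(c)
    morlet_power_channel(recording$signal[c, ], plan$wl, plan$nf_pad))
  names(power) <- recording$labels
  structure(list(power = power, freqs = params$freqs, fs = fs,
                 edges = plan$edges, labels = recording$labels,
                 t0 = recording$t0,
                 seams = attr(recording, "seams")),
            class = "bb_tfr")
}

#' @export
print.bb_tfr <- function(x, ...) {
  cat(sprintf("<bb_tfr> %d channels x %d freqs (%g-%g Hz) x %d samples @ %g Hz\n",
              length(x$power), length(x$freqs), min(x$freqs), max(x$freqs),
              ncol(x$power[[1L]]), x$fs))
  invisible(x)
}
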