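# Shared test helpers: a literal per-sample reference implementation of
# the burst-detection rules, and small constructors for hand-built
# time-frequency objects.

# Reference detector: direct per-sample evaluation of
#   (1) power strictly greater than factor x median over valid samples
#   (2) delete suprathreshold runs shorter than min_cycles / f seconds,
# written with explicit loops, independent of the package's rle-based path.
ref_detect_channel <- function(powmat, freqs, fs, factor, min_cycles,
                               edges) {
  nf <- nrow(powmat); n <- ncol(powmat)
  tf_mask <- matrix(FALSE, nf, n)
  for (i in seq_len(nf)) {
    lo <- edges[i] + 1L; hi <- n - edges[i]
    if (hi <= lo) next
    thr <- factor * median(powmat[i, lo:hi])
    sup <- logical(n)
    for (t in lo:hi) sup[t] <- powmat[i, t] > thr
    min_len <- min_cycles / freqs[i] * fs
    t <- 1L
    while (t <= n) {
      if (sup[t]) {
        u <- t
        while (u < n && sup[u + 1L]) u <- u + 1L
        if ((u - t + 1L) >= min_len - 1e-9) tf_mask[i, t:u] <- TRUE
        t <- u + 1L
      } else t <- t + 1L
    }
  }
  list(tf_mask = tf_mask, series = apply(tf_mask, 2L, any))
}

# wrap a list of power matrices as a bb_tfr with zero edge exclusion
make_tfr <- function(power_list, freqs, fs, edges = rep(0L, length(freqs))) {
  structure(list(power = power_list, freqs = freqs, fs = fs,
                 edges = as.integer(edges),
                 labels = paste0("ch", seq_along(power_list)),
                 t0 = 0, seams = NULL),
            class = "bb_tfr")
}

# detection params whose frequency grid is exactly `freqs`
params_for <- function(freqs, ...) {
  p <- detection_params(f_lo = min(freqs), f_hi = max(freqs) + 0.5,
                        f_step = if (length(freqs) > 1)
                          diff(freqs)[1] else 1, ...)
  p$freqs <- freqs
  p
}

# log-log periodogram slope of a time series over [f_lo, f_hi] Hz
spectral_slope <- function(x, fs, f_lo = 1, f_hi = 100) {
  n <- length(x)
  P <- Mod(fft(x))^2 / n
  f <- (seq_len(n) - 1L) * fs / n
  sel <- f >= f_lo & f <= f_hi & seq_len(n) <= n / 2
  # average the periodogram in log-spaced bins to stabilize the fit
  lf <- log10(f[sel]); lp <- log10(P[sel])
  bins <- cut(lf, breaks = 40)
  bf <- tapply(lf, bins, mean); bp <- tapply(lp, bins, mean)
  ok <- is.finite(bf) & is.finite(bp)
  unname(coef(lm(bp[ok] ~ bf[ok]))[2L])
}

# matched atoms <-> detected segments: overlap >= 50% of the shorter
match_atoms <- function(atoms, segments, channel_labels = NULL) {
  if (is.null(channel_labels))
    channel_labels <- unique(c(atoms$channel, segments$channel))
  hit <- logical(nrow(atoms))
  used <- logical(nrow(segments))
  for (lb in channel_labels) {
    ai <- which(atoms$channel == lb)
    si <- which(segments$channel == lb)
    if (!length(ai) || !length(si)) next
    for (k in ai) {
      ov <- pmin(segments$offset_s[si], atoms$offset_s[k]) -
        pmax(segments$onset_s[si], atoms$onset_s[k])
      shorter <- pmin(segments$offset_s[si] - segments$onset_s[si],
                      atoms$offset_s[k] - atoms$onset_s[k])
      j <- si[ov > 0 & ov >= 0.5 * shorter]
      if (length(j)) {
        hit[k] <- TRUE
        used[j] <- TRUE
      }
    }
  }
  list(recall = mean(hit), precision = mean(used),
       hit = hit, used = used)
}
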