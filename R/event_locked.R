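#' Epoch the binary burst series around behavioral events
#'
#' Cuts the continuous binary burst time series into trials time-locked
#' to each event, inclusive at both window edges (a `[-3, 3]` s window at
#' 1 kHz yields 6001 samples). Trials whose window extends beyond the
#' valid (edge-trimmed) data or crosses a concatenation seam are dropped
#' and counted, never zero-padded.
#'
#' @param mask a `bb_burstmask`, or a logical channels x samples matrix.
#' @param events a [bb_events()] or numeric vector of event times (s), on
#'   the same clock as the series.
#' @param window length-2 numeric, epoch window in seconds relative to
#'   the event (default `c(-3, 3)`).
#' @param fs,t0,valid,seams only needed when `mask` is a bare matrix.
#' @return An object of class `bb_raster`: `raster` (list, one trials x
#'   samples logical matrix per channel), `times` (sample times relative
#'   to the event), `events_used`, `n_dropped`, `fs`, `window`.
#' @export
epoch_bursts <- function(mask, events, window = c(-3, 3), fs = NULL,
                         t0 = 0, valid = NULL, seams = integer(0)) {
  if (inherits(mask, "bb_burstmask")) {
    series <- mask$series; fs <- mask$fs; t0 <- mask$t0
    valid <- mask$valid; seams <- mask$seams
  } else {
    series <- mask
    if (is.null(fs)) stop("`fs` is required when `mask` is a matrix")
    if (is.null(valid)) valid <- c(1L, ncol(series))
  }
  stopifnot(length(window) == 2L, window[2L] > window[1L])
  ev <- as_event_times(events)
  if (!length(ev)) stop("no events to epoch around")
  lo_off <- round(window[1L] * fs)
  hi_off <- round(window[2L] * fs)
  nsamp <- hi_off - lo_off + 1L
  i0 <- round((ev - t0) * fs)              # 0-based event sample
  a <- i0 + lo_off                          # 0-based first sample
  b <- i0 + hi_off
  ok <- a + 1L >= valid[1L] & b + 1L <= valid[2L]
  if (length(seams)) {
    crosses <- vapply(seq_along(ev), function(j)
      any(seams > a[j] & seams <= b[j]), TRUE)
    ok <- ok & !crosses
  }
  if (!any(ok)) stop("zero usable trials: every epoch window falls ",
                     "outside valid data or crosses a seam")
  keep <- which(ok)
  raster <- lapply(seq_len(nrow(series)), function(c) {
    out <- matrix(FALSE, length(keep), nsamp)
    for (j in seq_along(keep)) {
      out[j, ] <- series[c, (a[keep[j]] + 1L):(b[keep[j]] + 1L)]
    }
    out
  })
  names(raster) <- rownames(series)
  structure(list(raster = raster,
                 times = seq(lo_off, hi_off) / fs,
                 events_used = ev[keep],
                 n_dropped = sum(!ok),
                 fs = fs, window = window),
            class = "bb_raster")
}

#' @export
print.bb_raster <- function(x, ...) {
  cat(sprintf("<bb_raster> %d channels, %d trials x %d samples, window [%g, %g] s (%d dropped)\n",
              length(x$raster), nrow(x$raster[[1L]]), ncol(x$raster[[1L]]),
              x$window[1L], x$window[2L], x$n_dropped))
  invisible(x)
}

#' Burst probability index (BPI)
#'
#' The trial-averaged probability of being inside a burst as a function
#' of time relative to the event, baseline-corrected by subtracting the
#' median of the trial average across the full epoch time course.
#'
#' @param raster a `bb_raster` from [epoch_bursts()].
#' @return An object of class `bb_bpi`: `times`, `raw` (channels x
#'   samples trial-average, in `[0, 1]`), `baseline` (per-channel median
#'   of `raw` over time), `bpi` (`raw - baseline`), `n_trials`.
#' @export
compute_bpi <- function(raster) {
  stopifnot(inherits(raster, "bb_raster"))
  raw <- t(vapply(raster$raster, colMeans, numeric(ncol(raster$raster[[1L]]))))
  baseline <- apply(raw, 1L, stats::median)
  structure(list(times = raster$times, raw = raw, baseline = baseline,
                 bpi = raw - baseline, n_trials = nrow(raster$raster[[1L]]),
                 labels = names(raster$raster)),
            class = "bb_bpi")
}

#' @export
print.bb_bpi <- function(x, ...) {
  cat(sprintf("<bb_bpi> %d channels x %d time points (%d trials), bpi range [%.3f, %.3f]\n",
              nrow(x$bpi), ncol(x$bpi), x$n_trials, min(x$bpi), max(x$bpi)))
  invisible(x)
}

#' Suppression/rebound extrema of the BPI
#'
#' Minimum and maximum of the baseline-corrected burst probability within
#' a peri-event search window, with the time of their first occurrence
#' (ties broken by the earliest time point).
#'
#' @param bpi a `bb_bpi` from [compute_bpi()].
#' @param search_window length-2 numeric window in seconds (default
#'   `c(-1, 1)`); must lie within the epoch window.
#' @return Data frame with one row per channel: `channel`, `min_value`,
#'   `min_latency_s`, `max_value`, `max_latency_s`.
#' @export
bpi_extrema <- function(bpi, search_window = c(-1, 1)) {
  stopifnot(inherits(bpi, "bb_bpi"), length(search_window) == 2L)
  sel <- bpi$times >= search_window[1L] - 1e-9 &
    bpi$times <= search_window[2L] + 1e-9
  if (!any(sel)) stop("search window lies outside the epoch window")
  tt <- bpi$times[sel]
  sub <- bpi$bpi[, sel, drop = FALSE]
  imin <- apply(sub, 1L, which.min)  # which.min/max return first occurrence
  imax <- apply(sub, 1L, which.max)
  data.frame(channel = if (is.null(bpi$labels))
    paste0("ch", seq_len(nrow(sub))) else bpi$labels,
    min_value = sub[cbind(seq_len(nrow(sub)), imin)],
    min_latency_s = tt[imin],
    max_value = sub[cbind(seq_len(nrow(sub)), imax)],
    max_latency_s = tt[imax])
}

#' Touch-to-burst onset and burst offset-to-touch latencies
#'
#' For each event and channel: the time to the next burst onset at or
#' after the event and the time since the most recent burst offset at or
#' before it. Events occurring inside an ongoing burst skip that burst in
#' both directions (the latencies refer to the neighboring distinct
#' bursts); the within-burst co-occurrence itself is quantified by the
#' intra-burst touch rate instead. Latencies whose span crosses a
#' concatenation seam are set to `NA`.
#'
#' @param segments data frame from [extract_segments()].
#' @param events a [bb_events()] or numeric vector of event times (s).
#' @param seams_s numeric vector of seam times in seconds (masked clock).
#' @param labels channel labels defining output order.
#' @return Data frame with one row per channel x event: `channel`,
#'   `event_time`, `to_next_onset_s`, `from_prev_offset_s` (`NA` when no
#'   qualifying burst exists in the searched direction).
#' @export
touch_burst_latencies <- function(segments, events, seams_s = numeric(0),
                                  labels = NULL) {
  ev <- as_event_times(events)
  if (is.null(labels)) labels <- unique(segments$channel)
  out <- lapply(labels, function(lb) {
    seg <- segments[segments$channel == lb, , drop = FALSE]
    seg <- seg[order(seg$onset_s), , drop = FALSE]
    res <- data.frame(channel = rep(lb, length(ev)), event_time = ev,
                      to_next_onset_s = NA_real_,
                      from_prev_offset_s = NA_real_)
    if (!nrow(seg)) return(res)
    on <- seg$onset_s; off <- seg$offset_s
    j <- findInterval(ev, on)               # on[j] <= t < on[j+1]
    inside <- j >= 1L & ifelse(j >= 1L, off[pmax(j, 1L)] > ev, FALSE)
    next_idx <- ifelse(inside, j + 1L, j + 1L)
    prev_idx <- ifelse(inside, j - 1L, j)
    nxt <- ifelse(next_idx <= nrow(seg), on[pmin(next_idx, nrow(seg))],
                  NA_real_)
    prv <- ifelse(prev_idx >= 1L, off[pmax(prev_idx, 1L)], NA_real_)
    res$to_next_onset_s <- nxt - ev
    res$from_prev_offset_s <- ev - prv
    if (length(seams_s)) {
      for (i in seq_along(ev)) {
        if (!is.na(res$to_next_onset_s[i]) &&
            any(seams_s > ev[i] & seams_s < ev[i] + res$to_next_onset_s[i]))
          res$to_next_onset_s[i] <- NA_real_
        if (!is.na(res$from_prev_offset_s[i]) &&
            any(seams_s > ev[i] - res$from_prev_offset_s[i] & seams_s < ev[i]))
          res$from_prev_offset_s[i] <- NA_real_
      }
    }
    res
  })
  do.call(rbind, out)
}
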