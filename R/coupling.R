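#' Intra-burst touch rate (BTR)
#'
#' The number of behavioral events occurring while a channel's burst
#' series is ON, divided by the channel's total burst duration in
#' seconds. An event is "inside a burst" when the binary series is TRUE
#' at the sample containing the event (floor to sample index); an event
#' on a burst's half-open offset sample counts as outside.
#'
#' @param mask a `bb_burstmask`, or logical channels x samples matrix.
#' @param events a [bb_events()] or numeric vector of event times (s).
#' @param fs,t0 only needed when `mask` is a bare matrix.
#' @return Data frame per channel: `label`, `btr` (touches per second of
#'   burst time; `NA` with `flagged = TRUE` when the channel has zero
#'   burst time), `n_in_burst`, `total_burst_s`.
#' @export
intra_burst_touch_rate <- function(mask, events, fs = NULL, t0 = 0) {
  if (inherits(mask, "bb_burstmask")) {
    series <- mask$series; fs <- mask$fs; t0 <- mask$t0
    labels <- mask$labels
  } else {
    series <- mask
    if (is.null(fs)) stop("`fs` is required when `mask` is a matrix")
    labels <- rownames(series)
    if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(series)))
  }
  ev <- as_event_times(events)
  s <- floor((ev - t0) * fs + 1e-9) + 1L     # sample containing the event
  s <- s[s >= 1L & s <= ncol(series)]
  out <- lapply(seq_len(nrow(series)), function(c) {
    tot <- sum(series[c, ]) / fs
    n_in <- if (length(s)) sum(series[c, s]) else 0L
    data.frame(label = labels[c],
               btr = if (tot > 0) n_in / tot else NA_real_,
               n_in_burst = n_in, total_burst_s = tot,
               flagged = tot == 0)
  })
  do.call(rbind, out)
}

#' Burst-behavior timing index (BBTI)
#'
#' Splits consecutive inter-event intervals into a WITH group (any burst
#' sample in the open interval between the two events) and a WITHOUT
#' group, and reports the log10 difference of the two group median
#' interval durations. Positive values mean intervals containing bursts
#' are longer. Intervals crossing a concatenation seam or extending
#' outside the valid sample range are excluded.
#'
#' @inheritParams intra_burst_touch_rate
#' @param valid,seams only needed when `mask` is a bare matrix: valid
#'   1-based sample range and 0-based seam sample indices.
#' @return Data frame per channel: `label`, `bbti` (`NA` with a warning
#'   when either group is empty), `n_with`, `n_without`,
#'   `median_with_s`, `median_without_s`.
#' @export
bbti <- function(mask, events, fs = NULL, t0 = 0, valid = NULL,
                 seams = integer(0)) {
  if (inherits(mask, "bb_burstmask")) {
    series <- mask$series; fs <- mask$fs; t0 <- mask$t0
    valid <- mask$valid; seams <- mask$seams
    labels <- mask$labels
  } else {
    series <- mask
    if (is.null(fs)) stop("`fs` is required when `mask` is a matrix")
    if (is.null(valid)) valid <- c(1L, ncol(series))
    labels <- rownames(series)
    if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(series)))
  }
  ev <- as_event_times(events)
  if (length(ev) < 2L) stop("need at least 2 events to form intervals")
  t1 <- ev[-length(ev)]
  t2 <- ev[-1L]
  # samples strictly inside the open interval (t1, t2)
  a <- floor((t1 - t0) * fs + 1e-9) + 2L     # first sample fully after t1
  b <- ceiling((t2 - t0) * fs - 1e-9)        # last sample strictly before t2
  usable <- a + 1L >= valid[1L] + 1L & b <= valid[2L] & b >= a
  usable <- usable & t1 >= t0 & t2 <= t0 + ncol(series) / fs
  if (length(seams)) {
    for (i in which(usable)) {
      if (any(seams > a[i] - 1L & seams <= b[i])) usable[i] <- FALSE
    }
  }
  dt <- t2 - t1
  out <- lapply(seq_len(nrow(series)), function(c) {
    cs <- c(0L, cumsum(series[c, ]))     # cs[j + 1] = sum of first j samples
    has_burst <- rep(FALSE, length(dt))
    ii <- which(usable)
    has_burst[ii] <- (cs[b[ii] + 1L] - cs[a[ii]]) > 0L
    w <- dt[usable & has_burst]
    wo <- dt[usable & !has_burst]
    val <- if (length(w) && length(wo))
      log10(stats::median(w)) - log10(stats::median(wo)) else NA_real_
    if (is.na(val) && (length(w) || length(wo)))
      warning("channel ", labels[c], ": one BBTI group is empty")
    data.frame(label = labels[c], bbti = val,
               n_with = length(w), n_without = length(wo),
               median_with_s = if (length(w)) stats::median(w) else NA_real_,
               median_without_s = if (length(wo)) stats::median(wo)
               else NA_real_)
  })
  do.call(rbind, out)
}
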