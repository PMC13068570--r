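#' Behaviorally inactive segment mask
#'
#' Marks for removal every stretch of time that is far from all
#' behavioral events: a time point is removed iff its distance to the
#' preceding event AND to the following event both exceed `threshold_s`.
#' Stretches before the first and after the last event are treated as
#' having no event on that side (infinite distance), so recording edges
#' far from any event are removable.
#'
#' @param events a [bb_events()] or numeric vector of event times (s).
#' @param span length-2 numeric, recording span `[start, end)` in seconds.
#' @param threshold_s removal threshold in seconds (default 30).
#' @return An object of class `bb_mask`: list with `keep` (k x 2 matrix
#'   of kept `[start, end)` intervals, non-overlapping and sorted),
#'   `removed` (same for removed intervals) and `span`.
#' @examples
#' m <- inactive_segment_mask(c(10, 100), span = c(0, 110), threshold_s = 30)
#' m$keep     # [0, 40) and [70, 110)
#' @export
inactive_segment_mask <- function(events, span, threshold_s = 30) {
  stopifnot(length(span) == 2L, span[2L] > span[1L], threshold_s > 0)
  ev <- as_event_times(events)
  ev <- ev[ev >= span[1L] & ev <= span[2L]]
  if (!length(ev)) {
    warning("no events within span: entire recording removed")
    return(structure(list(keep = matrix(numeric(0), 0L, 2L),
                          removed = matrix(span, 1L, 2L, byrow = TRUE),
                          span = span),
                     class = "bb_mask"))
  }
  # A point t is removed iff (t - prev_event > thr) AND (next_event - t > thr).
  # Between consecutive events e_i, e_{i+1} the removed set is the open
  # interval (e_i + thr, e_{i+1} - thr); before the first event it is
  # [start, e_1 - thr); after the last, (e_k + thr, end).
  rem <- list()
  if (ev[1L] - threshold_s > span[1L])
    rem[[length(rem) + 1L]] <- c(span[1L], ev[1L] - threshold_s)
  if (length(ev) > 1L) {
    lo <- ev[-length(ev)] + threshold_s
    hi <- ev[-1L] - threshold_s
    ok <- hi > lo
    for (i in which(ok)) rem[[length(rem) + 1L]] <- c(lo[i], hi[i])
  }
  if (ev[length(ev)] + threshold_s < span[2L])
    rem[[length(rem) + 1L]] <- c(ev[length(ev)] + threshold_s, span[2L])
  removed <- if (length(rem)) do.call(rbind, rem) else matrix(numeric(0), 0L, 2L)
  keep <- interval_complement(removed, span)
  structure(list(keep = keep, removed = removed, span = span),
            class = "bb_mask")
}

# complement of sorted disjoint intervals within span
interval_complement <- function(intervals, span) {
  if (!nrow(intervals)) return(matrix(span, 1L, 2L, byrow = TRUE))
  edges <- c(span[1L], t(intervals), span[2L])
  keep <- matrix(edges, ncol = 2L, byrow = TRUE)
  keep[keep[, 2L] > keep[, 1L], , drop = FALSE]
}

#' @export
print.bb_mask <- function(x, ...) {
  kept <- sum(x$keep[, 2L] - x$keep[, 1L])
  cat(sprintf("<bb_mask> keep %.1f of %.1f s in %d interval%s\n",
              kept, diff(x$span), nrow(x$keep),
              if (nrow(x$keep) == 1) "" else "s"))
  invisible(x)
}

#' Full-span (identity) mask
#' @param span length-2 numeric span in seconds.
#' @return A `bb_mask` keeping everything.
#' @export
full_mask <- function(span) {
  structure(list(keep = matrix(span, 1L, 2L, byrow = TRUE),
                 removed = matrix(numeric(0), 0L, 2L), span = span),
            class = "bb_mask")
}

#' Write / read a segment mask as a two-column table of kept intervals
#' @param mask a `bb_mask`.
#' @param path file path.
#' @return `path` (write) or a `bb_mask` (read).
#' @export
write_mask <- function(mask, path) {
  utils::write.table(
    data.frame(start_s = mask$keep[, 1L], end_s = mask$keep[, 2L]),
    path, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname write_mask
#' @param span recording span, required to reconstruct removed intervals.
#' @export
read_mask <- function(path, span) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  keep <- as.matrix(df[, c("start_s", "end_s")])
  dimnames(keep) <- NULL
  removed <- interval_complement(keep, span)
  structure(list(keep = keep, removed = removed, span = span),
            class = "bb_mask")
}

#' Apply a segment mask to a recording
#'
#' Concatenates the kept segments and returns an index map translating
#' times between the original and the masked clock. Sample indices are
#' 0-based and intervals half-open, so a kept interval `[a, b)` at
#' sampling rate fs contributes samples `floor(a*fs) .. floor(b*fs)-1`.
#' Seam positions (masked-clock sample indices where non-contiguous
#' segments meet) are recorded so that downstream interval statistics can
#' refuse to span them.
#'
#' @param recording a [bb_recording()].
#' @param mask a `bb_mask` from [inactive_segment_mask()] or [full_mask()].
#' @return A list: `recording` (masked), `seams` (0-based masked sample
#'   indices at which a new segment starts, excluding 0), `map` (data
#'   frame of kept runs with original/masked start samples), and the
#'   total `kept_s` seconds.
#' @export
apply_mask <- function(recording, mask) {
  stopifnot(inherits(recording, "bb_recording"), inherits(mask, "bb_mask"))
  fs <- recording$fs
  n <- ncol(recording$signal)
  if (!nrow(mask$keep)) stop("mask keeps nothing; cannot apply")
  t0 <- recording$t0
  # sample runs (0-based, half-open) for each kept interval
  s0 <- pmax(0L, floor((mask$keep[, 1L] - t0) * fs + 1e-9))
  s1 <- pmin(n, floor((mask$keep[, 2L] - t0) * fs + 1e-9))
  ok <- s1 > s0
  s0 <- as.integer(s0[ok]); s1 <- as.integer(s1[ok])
  len <- s1 - s0
  m0 <- cumsum(c(0L, len[-length(len)]))  # masked start of each run
  idx <- unlist(mapply(function(a, b) seq.int(a + 1L, b), s0, s1,
                       SIMPLIFY = FALSE))
  out <- recording
  out$signal <- recording$signal[, idx, drop = FALSE]
  out$t0 <- 0
  # a seam exists where consecutive runs are non-contiguous in the original
  contiguous <- c(TRUE, s0[-1L] == s1[-length(s1)])
  seams <- m0[!contiguous]
  list(recording = out,
       seams = as.integer(seams),
       map = data.frame(orig_start = s0, masked_start = m0, length = len),
       kept_s = sum(len) / fs)
}

#' Translate times between original and masked clocks
#'
#' @param times numeric vector of times in seconds.
#' @param map the `map` component returned by [apply_mask()].
#' @param fs sampling rate in Hz.
#' @param t0 original recording start time (s).
#' @return Times on the other clock; `NA` for times falling in removed
#'   segments (forward direction only).
#' @export
to_masked_time <- function(times, map, fs, t0 = 0) {
  s <- floor((times - t0) * fs + 1e-9)
  out <- rep(NA_real_, length(times))
  for (i in seq_len(nrow(map))) {
    inrun <- s >= map$orig_start[i] & s < map$orig_start[i] + map$length[i]
    out[inrun] <- (times[inrun] - t0) - map$orig_start[i] / fs +
      map$masked_start[i] / fs
  }
  out
}

#' @rdname to_masked_time
#' @export
to_original_time <- function(times, map, fs, t0 = 0) {
  s <- floor(times * fs + 1e-9)
  out <- rep(NA_real_, length(times))
  for (i in seq_len(nrow(map))) {
    inrun <- s >= map$masked_start[i] & s < map$masked_start[i] + map$length[i]
    out[inrun] <- times[inrun] - map$masked_start[i] / fs +
      map$orig_start[i] / fs + t0
  }
  out
}
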