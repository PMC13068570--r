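# Core of the burst detector, one channel at a time.
#
# Rules (applied per frequency, in this order):
#   1. threshold = threshold_factor x median of that frequency's power
#      over all valid samples of the whole recording (strict >)
#   2. suprathreshold runs shorter than min_cycles / f seconds are deleted
# The surviving runs populate the binary TF mask; the burst time series
# is the any-frequency collapse of that mask.
detect_core <- function(powmat, freqs, fs, params, edges) {
  n <- ncol(powmat)
  nf <- length(freqs)
  series <- logical(n)
  runs <- vector("list", nf)
  thresholds <- rep(NA_real_, nf)
  for (i in seq_len(nf)) {
    lo <- edges[i] + 1L
    hi <- n - edges[i]
    if (hi <= lo) next
    pw <- powmat[i, ]
    thr <- params$threshold_factor * stats::median(pw[lo:hi])
    thresholds[i] <- thr
    sup <- pw > thr
    if (edges[i] > 0L) {
      sup[seq_len(edges[i])] <- FALSE
      sup[(n - edges[i] + 1L):n] <- FALSE
    }
    if (!any(sup)) next
    r <- rle(sup)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    min_len <- params$min_cycles / freqs[i] * fs
    keep <- r$values & (r$lengths >= min_len - 1e-9)
    if (!any(keep)) next
    runs[[i]] <- data.frame(freq_idx = i, start = starts[keep],
                            end = ends[keep])
    for (k in which(keep)) series[starts[k]:ends[k]] <- TRUE
  }
  list(tf_runs = do.call(rbind, runs[!vapply(runs, is.null, TRUE)]),
       series = series, thresholds = thresholds)
}

#' Detect beta bursts in a time-frequency decomposition
#'
#' Applies the median-multiple power threshold and the minimum-cycles
#' duration rule per channel and frequency, producing a binary
#' time-frequency burst mask and its any-frequency collapse, the binary
#' burst time series.
#'
#' @param tf a `bb_tfr` from [tf_decompose()].
#' @param params a [detection_params()] (defaults must match those used
#'   for the decomposition grid).
#' @return An object of class `bb_burstmask`: `series` (channels x
#'   samples logical matrix), `tf_runs` (per channel, a data frame of
#'   surviving suprathreshold runs with columns `freq_idx`, `start`,
#'   `end`, 1-based inclusive sample indices), `thresholds`, `freqs`,
#'   `fs`, `edges`, `valid` (first/last sample of the series' valid
#'   range), `params`, `labels`, `t0`, `seams`.
#' @seealso [tf_mask_matrix()] to expand a channel's runs to a dense
#'   binary matrix, [extract_segments()] for burst segments.
#' @export
detect_bursts <- function(tf, params = detection_params()) {
  stopifnot(inherits(tf, "bb_tfr"), inherits(params, "bb_params"))
  if (!isTRUE(all.equal(tf$freqs, params$freqs)))
    stop("frequency grid of `tf` does not match `params`")
  nch <- length(tf$power)
  n <- ncol(tf$power[[1L]])
  series <- matrix(FALSE, nch, n, dimnames = list(tf$labels, NULL))
  tf_runs <- vector("list", nch)
  thresholds <- matrix(NA_real_, nch, length(tf$freqs),
                       dimnames = list(tf$labels, NULL))
  for (c in seq_len(nch)) {
    core <- detect_core(tf$power[[c]], tf$freqs, tf$fs, params, tf$edges)
    series[c, ] <- core$series
    tf_runs[c] <- list(core$tf_runs)
    thresholds[c, ] <- core$thresholds
  }
  names(tf_runs) <- tf$labels
  new_burstmask(series, tf_runs, thresholds, tf$freqs, tf$fs, tf$edges,
                params, tf$labels, tf$t0, tf$seams)
}

new_burstmask <- function(series, tf_runs, thresholds, freqs, fs, edges,
                          params, labels, t0, seams) {
  emax <- max(edges)
  structure(list(series = series, tf_runs = tf_runs,
                 thresholds = thresholds, freqs = freqs, fs = fs,
                 edges = edges, valid = c(emax + 1L, ncol(series) - emax),
                 params = params, labels = labels, t0 = t0,
                 seams = if (is.null(seams)) integer(0) else seams),
            class = "bb_burstmask")
}

#' @export
print.bb_burstmask <- function(x, ...) {
  vd <- valid_duration(x)
  occ <- rowMeans(x$series[, x$valid[1L]:x$valid[2L], drop = FALSE])
  cat(sprintf("<bb_burstmask> %d channels x %d samples @ %g Hz (valid %.1f s)\n",
              nrow(x$series), ncol(x$series), x$fs, vd))
  cat(sprintf("  occupancy: %.3f-%.3f (median %.3f)\n",
              min(occ), max(occ), stats::median(occ)))
  invisible(x)
}

#' Valid (edge-trimmed) duration of a burst mask, in seconds
#' @param mask a `bb_burstmask`.
#' @export
valid_duration <- function(mask) {
  (mask$valid[2L] - mask$valid[1L] + 1L) / mask$fs
}

#' Expand one channel's surviving runs to a dense binary TF matrix
#' @param mask a `bb_burstmask`.
#' @param channel channel index or label.
#' @return logical matrix, frequencies x samples.
#' @export
tf_mask_matrix <- function(mask, channel = 1L) {
  if (is.character(channel)) channel <- match(channel, mask$labels)
  out <- matrix(FALSE, length(mask$freqs), ncol(mask$series))
  runs <- mask$tf_runs[[channel]]
  if (!is.null(runs) && nrow(runs)) {
    for (k in seq_len(nrow(runs)))
      out[runs$freq_idx[k], runs$start[k]:runs$end[k]] <- TRUE
  }
  out
}

# burst segments for one channel given its collapsed series and, when
# available, the TF power for peak extraction
segments_channel <- function(series_vec, tf_runs, powmat, freqs, fs, t0,
                             valid, seams, label) {
  r <- rle(as.vector(series_vec))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  if (!length(on)) {
    return(data.frame(channel = character(0), onset_s = numeric(0),
                      offset_s = numeric(0), duration_s = numeric(0),
                      peak_power = numeric(0), peak_freq = numeric(0),
                      peak_time_s = numeric(0), seam_clipped = logical(0)))
  }
  seg_start <- starts[on]
  seg_end <- ends[on]
  pk_pow <- pk_frq <- pk_tim <- rep(NA_real_, length(on))
  if (!is.null(powmat) && !is.null(tf_runs) && nrow(tf_runs)) {
    for (j in seq_along(on)) {
      inseg <- tf_runs$start <= seg_end[j] & tf_runs$end >= seg_start[j]
      best <- -Inf
      for (k in which(inseg)) {
        cols <- max(tf_runs$start[k], seg_start[j]):min(tf_runs$end[k], seg_end[j])
        pv <- powmat[tf_runs$freq_idx[k], cols]
        m <- which.max(pv)
        if (pv[m] > best) {
          best <- pv[m]
          pk_pow[j] <- pv[m]
          pk_frq[j] <- freqs[tf_runs$freq_idx[k]]
          pk_tim[j] <- t0 + (cols[m] - 1L) / fs
        }
      }
    }
  }
  clipped <- vapply(seq_along(on), function(j) {
    touches_edge <- seg_start[j] <= valid[1L] || seg_end[j] >= valid[2L]
    # seams are 0-based sample indices where a new segment begins
    crosses_seam <- any(seams >= seg_start[j] & seams <= seg_end[j])
    touches_edge || crosses_seam
  }, TRUE)
  data.frame(channel = label,
             onset_s = t0 + (seg_start - 1L) / fs,
             offset_s = t0 + seg_end / fs,
             duration_s = (seg_end - seg_start + 1L) / fs,
             peak_power = pk_pow, peak_freq = pk_frq, peak_time_s = pk_tim,
             seam_clipped = clipped)
}

#' Extract burst segments from a burst mask
#'
#' One segment per maximal run of the collapsed binary series per
#' channel, half-open in time: a run of samples `i..j` (1-based) becomes
#' `[t0 + (i-1)/fs, t0 + j/fs)`. Peak power, frequency, and time are
#' taken from the TF maximum inside the segment's suprathreshold support
#' when `tf` is supplied. Segments touching the valid-range edge or
#' crossing a concatenation seam are flagged `seam_clipped`.
#'
#' @param mask a `bb_burstmask`.
#' @param tf the matching `bb_tfr`, or `NULL` to skip peak extraction.
#' @return A data frame with one row per burst: `channel`, `onset_s`,
#'   `offset_s`, `duration_s`, `peak_power`, `peak_freq`, `peak_time_s`,
#'   `seam_clipped`.
#' @export
extract_segments <- function(mask, tf = NULL) {
  stopifnot(inherits(mask, "bb_burstmask"))
  out <- lapply(seq_len(nrow(mask$series)), function(c) {
    segments_channel(mask$series[c, ], mask$tf_runs[[c]],
                     if (is.null(tf)) NULL else tf$power[[c]],
                     mask$freqs, mask$fs, mask$t0, mask$valid,
                     mask$seams, mask$labels[c])
  })
  do.call(rbind, out)
}

#' Write burst segments as a delimited table
#' @param segments data frame from [extract_segments()].
#' @param path output path.
#' @export
write_segments <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", row.names = FALSE)
  invisible(path)
}
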