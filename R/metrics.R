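#' Burst occupancy per channel
#'
#' The fraction of searchable recording time a channel spends inside
#' detected bursts: total burst duration divided by the valid recording
#' duration, equivalently the mean of the binary burst series over valid
#' samples.
#'
#' @param mask a `bb_burstmask` from [detect_bursts()].
#' @param valid_duration_s duration to normalize by, in seconds; defaults
#'   to the mask's edge-trimmed valid duration.
#' @return Named numeric vector of occupancies in `[0, 1]`.
#' @export
burst_occupancy <- function(mask, valid_duration_s = valid_duration(mask)) {
  stopifnot(inherits(mask, "bb_burstmask"))
  if (valid_duration_s <= 0) stop("valid duration must be positive")
  cols <- mask$valid[1L]:mask$valid[2L]
  rowSums(mask$series[, cols, drop = FALSE]) / (valid_duration_s * mask$fs)
}

#' Per-channel burst summary metrics
#'
#' Burst count, median duration, and rate per channel from a segment
#' table. The median is the per-channel median over individual burst
#' durations; channels with no bursts report `NA`. Segments flagged
#' `seam_clipped` (clipped by a mask seam or the valid-range edge) are
#' excluded from the duration median but counted.
#'
#' @param segments data frame from [extract_segments()].
#' @param valid_duration_s searchable duration in seconds.
#' @param labels channel labels defining row order (defaults to the
#'   labels present in `segments`).
#' @return Data frame with columns `label`, `bo`, `n_bursts`,
#'   `median_duration_s`, `rate_hz`.
#' @export
channel_metrics <- function(segments, valid_duration_s, labels = NULL) {
  if (valid_duration_s <= 0) stop("valid duration must be positive")
  if (is.null(labels)) labels <- unique(segments$channel)
  out <- lapply(labels, function(lb) {
    seg <- segments[segments$channel == lb, , drop = FALSE]
    whole <- seg[!seg$seam_clipped, , drop = FALSE]
    data.frame(label = lb,
               bo = sum(seg$duration_s) / valid_duration_s,
               n_bursts = nrow(seg),
               median_duration_s = if (nrow(whole))
                 stats::median(whole$duration_s) else NA_real_,
               rate_hz = nrow(seg) / valid_duration_s)
  })
  do.call(rbind, out)
}

#' z-normalize a per-channel map across electrodes
#'
#' Standardizes a vector of per-channel scalars to zero mean and unit
#' sample standard deviation (n - 1 denominator) across channels,
#' exposing the relative topography of the map.
#'
#' @param values numeric vector, one value per channel (length >= 2).
#' @return z-scores of the same length; all zeros (with a warning) if the
#'   input is constant.
#' @examples
#' znorm_channels(c(1, 2, 3))  # -1 0 1
#' @export
znorm_channels <- function(values) {
  if (length(values) < 2L)
    stop("z-normalization across electrodes needs at least 2 channels")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    warning("constant map: z-scores set to 0")
    return(rep(0, length(values)))
  }
  (values - mean(values)) / s
}
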