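#' Fit the beta-burst model of a continuous recording
#'
#' The package's central entry point: detects beta bursts channel by
#' channel (Morlet power, median-multiple threshold, minimum-cycles
#' rule) and, when a behavioral event train is supplied, computes every
#' burst-behavior statistic of the analysis: burst occupancy and its
#' across-electrode z-scores, the touch-locked burst probability index
#' with suppression/rebound extrema, touch-burst latencies, the
#' intra-burst touch rate, and the burst-behavior timing index.
#'
#' Detection streams one channel at a time, so memory stays flat in the
#' number of channels. When `mask_inactive = TRUE` (and events are
#' given), stretches farther than `inactive_threshold_s` from every
#' event are removed first and all event times are translated to the
#' masked clock; epochs and inter-touch intervals never span a
#' concatenation seam.
#'
#' @param recording a [bb_recording()].
#' @param events optional [bb_events()] or numeric vector of touch
#'   times (s) on the recording clock.
#' @param params a [detection_params()].
#' @param mask_inactive remove behaviorally inactive segments before
#'   detection (default `TRUE` when events are supplied).
#' @param inactive_threshold_s inactivity threshold in seconds
#'   (default 30).
#' @param epoch_window epoch window for the BPI, seconds (default
#'   `c(-3, 3)`).
#' @param extrema_window search window for BPI extrema, seconds
#'   (default `c(-1, 1)`).
#' @param keep_tf keep each channel's dense time-frequency power in the
#'   returned object (memory-hungry; default `FALSE`).
#' @return An object of class `beta_bursts`: list with `mask`
#'   (`bb_burstmask`), `segments`, `metrics` (per-channel table with
#'   `bo`, `bo_z`, counts, durations, and - when events are given -
#'   `btr`, `btr_z`, `bbti`, `bbti_z`), `bpi`, `extrema`, `latencies`,
#'   `coupling`, `events` (masked clock), `n_dropped_trials`,
#'   `valid_duration_s`, `params`, `call`.
#' @examples
#' cfg <- synth_config(n_channels = 2, duration_s = 60, seed = 1)
#' ses <- simulate_session(cfg)
#' fit <- beta_bursts(ses$recording, ses$events)
#' fit
#' coef(fit)
#' @export
beta_bursts <- function(recording, events = NULL,
                        params = detection_params(),
                        mask_inactive = !is.null(events),
                        inactive_threshold_s = 30,
                        epoch_window = c(-3, 3),
                        extrema_window = c(-1, 1),
                        keep_tf = FALSE) {
  stopifnot(inherits(recording, "bb_recording"))
  cl <- match.call()
  ev <- if (is.null(events)) NULL else as_event_times(events)
  seams <- integer(0)
  if (mask_inactive) {
    if (is.null(ev)) stop("`mask_inactive = TRUE` requires events")
    span <- c(recording$t0, recording$t0 + rec_duration(recording))
    msk <- inactive_segment_mask(ev, span, inactive_threshold_s)
    applied <- apply_mask(recording, msk)
    ev <- to_masked_time(ev, applied$map, recording$fs, recording$t0)
    ev <- ev[!is.na(ev)]
    recording <- applied$recording
    seams <- applied$seams
  }
  fs <- recording$fs
  n <- ncol(recording$signal)
  plan <- morlet_plan(params$freqs, fs, params$wavelet_cycles, n)
  nch <- nrow(recording$signal)
  series <- matrix(FALSE, nch, n, dimnames = list(recording$labels, NULL))
  tf_runs <- vector("list", nch)
  thresholds <- matrix(NA_real_, nch, length(params$freqs))
  seg_list <- vector("list", nch)
  tf_keep <- if (keep_tf) vector("list", nch) else NULL
  emax <- max(plan$edges)
  valid <- c(emax + 1L, n - emax)
  for (c in seq_len(nch)) {
    pw <- morlet_power_channel(recording$signal[c, ], plan$wl, plan$nf_pad)
    core <- detect_core(pw, params$freqs, fs, params, plan$edges)
    series[c, ] <- core$series
    tf_runs[c] <- list(core$tf_runs)
    thresholds[c, ] <- core$thresholds
    seg_list[[c]] <- segments_channel(core$series, core$tf_runs, pw,
                                      params$freqs, fs, recording$t0,
                                      valid, seams, recording$labels[c])
    if (keep_tf) tf_keep[[c]] <- pw
  }
  names(tf_runs) <- recording$labels
  mask <- new_burstmask(series, tf_runs, thresholds, params$freqs, fs,
                        plan$edges, params, recording$labels,
                        recording$t0, seams)
  segments <- do.call(rbind, seg_list)
  vd <- valid_duration(mask)
  metrics <- channel_metrics(segments, vd, labels = recording$labels)
  metrics$bo <- as.numeric(burst_occupancy(mask))
  metrics$bo_z <- if (nch >= 2) znorm_channels(metrics$bo) else NA_real_

  bpi <- extrema <- latencies <- coupling <- NULL
  n_dropped <- NA_integer_
  if (!is.null(ev) && length(ev)) {
    raster <- try(epoch_bursts(mask, ev, window = epoch_window),
                  silent = TRUE)
    if (!inherits(raster, "try-error")) {
      bpi <- compute_bpi(raster)
      extrema <- bpi_extrema(bpi, extrema_window)
      n_dropped <- raster$n_dropped
    }
    latencies <- touch_burst_latencies(segments, ev,
                                       seams_s = seams / fs,
                                       labels = recording$labels)
    btr_df <- intra_burst_touch_rate(mask, ev)
    bbti_df <- suppressWarnings(bbti(mask, ev))
    coupling <- merge(btr_df[, c("label", "btr", "n_in_burst",
                                 "total_burst_s")],
                      bbti_df, by = "label", sort = FALSE)
    coupling <- coupling[match(recording$labels, coupling$label), ]
    metrics$btr <- coupling$btr
    metrics$btr_z <- if (nch >= 2 && !anyNA(coupling$btr))
      znorm_channels(coupling$btr) else NA_real_
    metrics$bbti <- coupling$bbti
    metrics$bbti_z <- if (nch >= 2 && !anyNA(coupling$bbti))
      znorm_channels(coupling$bbti) else NA_real_
  }
  structure(list(mask = mask, segments = segments, metrics = metrics,
                 bpi = bpi, extrema = extrema, latencies = latencies,
                 coupling = coupling, events = ev,
                 n_dropped_trials = n_dropped, valid_duration_s = vd,
                 seams = seams, params = params,
                 tf_power = tf_keep, call = cl),
            class = "beta_bursts")
}

#' @export
print.beta_bursts <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("Beta-burst fit: %d channels, %.1f s valid, %d bursts\n",
              nrow(m), x$valid_duration_s, sum(m$n_bursts)))
  cat(sprintf("  occupancy %.3f-%.3f, median burst duration %.0f ms\n",
              min(m$bo), max(m$bo),
              1000 * stats::median(m$median_duration_s, na.rm = TRUE)))
  if (!is.null(x$events))
    cat(sprintf("  %d events, %s trials in BPI raster\n",
                length(x$events),
                if (is.null(x$bpi)) "no" else x$bpi$n_trials))
  invisible(x)
}

#' @export
summary.beta_bursts <- function(object, ...) {
  out <- list(metrics = object$metrics, extrema = object$extrema,
              n_bursts = sum(object$metrics$n_bursts),
              valid_duration_s = object$valid_duration_s)
  class(out) <- "summary.beta_bursts"
  out
}

#' @export
print.summary.beta_bursts <- function(x, ...) {
  cat("Per-channel burst metrics:\n")
  print(x$metrics, digits = 3, row.names = FALSE)
  if (!is.null(x$extrema)) {
    cat("\nBPI extrema (search window):\n")
    print(x$extrema, digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.beta_bursts <- function(object, ...) {
  m <- object$metrics
  out <- as.matrix(m[, setdiff(names(m), "label"), drop = FALSE])
  rownames(out) <- m$label
  out
}

#' @export
plot.beta_bursts <- function(x, channels = NULL, ...) {
  if (is.null(x$bpi)) {
    graphics::barplot(x$metrics$bo, names.arg = x$metrics$label,
                      ylab = "burst occupancy", las = 2, ...)
    return(invisible(x))
  }
  if (is.null(channels)) channels <- seq_len(min(4L, nrow(x$bpi$bpi)))
  if (is.character(channels)) channels <- match(channels, x$metrics$label)
  old <- graphics::par(mfrow = c(length(channels), 1L),
                       mar = c(3, 4, 1, 1))
  on.exit(graphics::par(old))
  for (c in channels) {
    graphics::plot(x$bpi$times, x$bpi$bpi[c, ], type = "l",
                   xlab = "time from touch (s)", ylab = "BPI",
                   main = x$metrics$label[c], ...)
    graphics::abline(h = 0, v = 0, lty = 3)
  }
  invisible(x)
}

#' Run one analysis from a configuration
#'
#' Configuration-driven single-session pipeline: either reads a
#' recording and events from disk or simulates a synthetic session,
#' fits [beta_bursts()], and writes every result table plus a JSON run
#' manifest to `out_dir`.
#'
#' The config is a YAML file or an equivalent named list with exactly
#' one of `input: {recording, events, dialect}` or `synth:` (fields of
#' [synth_config()]), plus optional `detection:` (fields of
#' [detection_params()]), `epoch_window`, `extrema_window`,
#' `inactive_threshold_s`, `mask_inactive`, and `seed` (required with
#' `synth`, overriding any seed inside the synth block).
#'
#' @param config path to a YAML file, or a named list.
#' @param out_dir output directory (created if missing).
#' @return The fitted `beta_bursts` object, invisibly; tables are
#'   written as `metrics.tsv`, `segments.tsv`, `bpi.tsv`,
#'   `extrema.tsv`, `latencies.tsv`, `coupling.tsv`, `manifest.json`.
#' @export
run_single <- function(config, out_dir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  has_input <- !is.null(cfg$input)
  has_synth <- !is.null(cfg$synth)
  if (has_input == has_synth)
    stop("config must contain exactly one of `input` or `synth`")
  det <- do.call(detection_params,
                 if (is.null(cfg$detection)) list() else cfg$detection)
  if (has_input) {
    rec <- read_recording(cfg$input$recording,
                          dialect = if (is.null(cfg$input$dialect))
                            "native" else cfg$input$dialect)
    ev <- if (is.null(cfg$input$events)) NULL else
      read_events(cfg$input$events)
  } else {
    sargs <- cfg$synth
    if (!is.null(cfg$seed)) sargs$seed <- cfg$seed
    scfg <- do.call(synth_config, sargs)
    ses <- simulate_session(scfg, signal = TRUE)
    rec <- ses$recording
    ev <- ses$events
  }
  fit <- beta_bursts(
    rec, ev, params = det,
    mask_inactive = if (is.null(cfg$mask_inactive)) !is.null(ev)
    else isTRUE(cfg$mask_inactive),
    inactive_threshold_s = if (is.null(cfg$inactive_threshold_s)) 30
    else cfg$inactive_threshold_s,
    epoch_window = if (is.null(cfg$epoch_window)) c(-3, 3)
    else as.numeric(cfg$epoch_window),
    extrema_window = if (is.null(cfg$extrema_window)) c(-1, 1)
    else as.numeric(cfg$extrema_window))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       row.names = FALSE)
    name
  }
  files <- c(wt(fit$metrics, "metrics.tsv"),
             wt(fit$segments, "segments.tsv"))
  if (!is.null(fit$bpi)) {
    nch <- nrow(fit$bpi$bpi)
    long <- data.frame(
      channel = rep(fit$bpi$labels, each = length(fit$bpi$times)),
      time_s = rep(fit$bpi$times, nch),
      raw = as.vector(t(fit$bpi$raw)),
      bpi = as.vector(t(fit$bpi$bpi)))
    files <- c(files, wt(long, "bpi.tsv"), wt(fit$extrema, "extrema.tsv"))
  }
  if (!is.null(fit$latencies))
    files <- c(files, wt(fit$latencies, "latencies.tsv"))
  if (!is.null(fit$coupling))
    files <- c(files, wt(fit$coupling, "coupling.tsv"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("betabursts")),
    r_version = R.version.string,
    detection = fit$params[c("f_lo", "f_hi", "f_step", "threshold_factor",
                             "min_cycles", "wavelet_cycles")],
    n_channels = nrow(fit$metrics),
    valid_duration_s = fit$valid_duration_s,
    n_events = length(fit$events),
    n_dropped_trials = fit$n_dropped_trials,
    n_seams = length(fit$seams),
    tables = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(fit)
}

#' Population-level inference over fitted sessions
#'
#' Pools a per-channel scalar (or the BPI time course) across fitted
#' participants and applies the analysis-appropriate correction:
#' Bonferroni-corrected one-sample t-tests for scalar channel maps,
#' spatio-temporal cluster bootstrap for channel x time BPI maps.
#'
#' @param fits list of `beta_bursts` objects with identical channel
#'   sets.
#' @param what one of `"bo"`, `"bo_z"`, `"btr"`, `"btr_z"`, `"bbti"`,
#'   `"bbti_z"`, `"extrema_min"`, `"extrema_max"` (scalar maps) or
#'   `"bpi"` (channels x time).
#' @param adjacency channel adjacency matrix; required for `"bpi"`.
#' @param alpha family-wise alpha.
#' @param n_boot bootstrap resamples for `"bpi"`.
#' @param seed seed for the bootstrap.
#' @return A `bb_statmap`.
#' @export
run_group <- function(fits, what = "bo_z", adjacency = NULL,
                      alpha = 0.05, n_boot = 1000, seed = 1) {
  stopifnot(length(fits) >= 2L)
  labs <- fits[[1L]]$metrics$label
  for (i in seq_along(fits)) {
    if (!identical(fits[[i]]$metrics$label, labs))
      stop("participant ", i, " has a different channel set")
  }
  if (what == "bpi") {
    if (is.null(adjacency)) stop("`adjacency` is required for BPI maps")
    nt <- length(fits[[1L]]$bpi$times)
    x <- array(NA_real_, c(length(fits), length(labs), nt))
    for (i in seq_along(fits)) x[i, , ] <- fits[[i]]$bpi$bpi
    return(cluster_bootstrap(x, adjacency, alpha = alpha,
                             n_boot = n_boot, seed = seed))
  }
  col <- switch(what,
                extrema_min = "min_value", extrema_max = "max_value",
                what)
  src <- if (what %in% c("extrema_min", "extrema_max")) "extrema"
  else "metrics"
  x <- t(vapply(fits, function(f) as.numeric(f[[src]][[col]]),
                numeric(length(labs))))
  group_t_map(x, alpha = alpha)
}
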