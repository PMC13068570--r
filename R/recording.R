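#' Construct a continuous multichannel recording
#'
#' A recording is the basic container for continuous neural time series:
#' a channels-by-samples numeric matrix, a sampling rate, unique channel
#' labels, optional 2D/3D channel positions (used to derive spatial
#' adjacency for cluster statistics), and a clock origin `t0` in seconds.
#'
#' @param signal numeric matrix, channels x samples (microvolt-typical,
#'   arbitrary units). A vector is treated as a single channel.
#' @param fs sampling rate in Hz, positive scalar.
#' @param labels character vector of unique channel labels; defaults to
#'   `"ch1" ... "chN"`.
#' @param positions optional numeric matrix (channels x 2 or 3) of channel
#'   coordinates, or `NULL`.
#' @param t0 recording start time in seconds on the common clock shared
#'   with behavioral events.
#' @return An object of class `bb_recording`.
#' @examples
#' rec <- bb_recording(matrix(rnorm(2000), 2), fs = 1000)
#' rec
#' @export
bb_recording <- function(signal, fs, labels = NULL, positions = NULL, t0 = 0) {
  if (is.vector(signal)) signal <- matrix(signal, nrow = 1L)
  if (!is.matrix(signal) || !is.numeric(signal))
    stop("`signal` must be a numeric matrix (channels x samples)")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive finite scalar (Hz)")
  nch <- nrow(signal)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nch))
  labels <- as.character(labels)
  if (length(labels) != nch)
    stop("number of channel labels (", length(labels),
         ") does not match number of signal rows (", nch, ")")
  if (anyDuplicated(labels))
    stop("duplicate channel labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  bad <- which(!is.finite(signal), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-finite sample(s) in signal, first at channel '",
         labels[bad[1L, 1L]], "', sample index ", bad[1L, 2L] - 1L)
  }
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    if (nrow(positions) != nch || !ncol(positions) %in% c(2L, 3L))
      stop("`positions` must be a channels x 2 or channels x 3 matrix")
    rownames(positions) <- labels
  }
  rownames(signal) <- labels
  structure(
    list(signal = signal, fs = fs, labels = labels,
         positions = positions, t0 = as.numeric(t0)),
    class = "bb_recording")
}

#' @export
print.bb_recording <- function(x, ...) {
  cat(sprintf("<bb_recording> %d channel%s x %d samples @ %g Hz (%.3f s, t0 = %g s)\n",
              nrow(x$signal), if (nrow(x$signal) == 1) "" else "s",
              ncol(x$signal), x$fs, ncol(x$signal) / x$fs, x$t0))
  cat("  channels:", paste(utils::head(x$labels, 8), collapse = ", "),
      if (length(x$labels) > 8) "..." else "", "\n")
  invisible(x)
}

#' Recording duration in seconds
#' @param recording a [bb_recording()].
#' @return scalar duration, `n_samples / fs`.
#' @export
rec_duration <- function(recording) ncol(recording$signal) / recording$fs

#' Read a recording from disk
#'
#' The native dialect is a pair of text files: `<path>` holds the signal
#' as a tab-separated numeric matrix (one row per channel, no header) and
#' `<path>.json` holds `{fs, labels, t0, positions}`. The `edf` dialect
#' reads 16-bit European Data Format files (continuous, unannotated).
#'
#' @param path file path of the signal matrix (native) or `.edf` file.
#' @param dialect `"native"` or `"edf"`.
#' @return A [bb_recording()]; sampling rate and labels come from the
#'   file header. Non-finite samples or invalid headers are rejected.
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, dialect = c("native", "edf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "edf") return(read_edf(path))
  hdr_path <- paste0(path, ".json")
  if (!file.exists(hdr_path)) stop("missing header file: ", hdr_path)
  hdr <- jsonlite::read_json(hdr_path, simplifyVector = TRUE)
  if (is.null(hdr$fs) || !is.numeric(hdr$fs) || hdr$fs <= 0)
    stop("header `fs` missing or not a positive number in ", hdr_path)
  sig <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                     colClasses = "numeric"))
  dimnames(sig) <- NULL
  pos <- if (!is.null(hdr$positions)) as.matrix(hdr$positions) else NULL
  bb_recording(sig, fs = hdr$fs, labels = hdr$labels, positions = pos,
               t0 = if (is.null(hdr$t0)) 0 else hdr$t0)
}

#' Write a recording to disk in the native dialect
#'
#' @param recording a [bb_recording()].
#' @param path output path for the signal matrix; the JSON header is
#'   written next to it as `<path>.json`.
#' @param digits significant digits kept in the text matrix.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, digits = 10) {
  stopifnot(inherits(recording, "bb_recording"))
  sig <- signif(recording$signal, digits)
  utils::write.table(sig, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  hdr <- list(fs = recording$fs, labels = recording$labels,
              t0 = recording$t0)
  if (!is.null(recording$positions))
    hdr$positions <- unname(recording$positions)
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Construct a behavioral event train
#'
#' Timestamps of discrete behavioral events (touchscreen touches) on the
#' same clock as the recording. Times are sorted and deduplicated.
#'
#' @param times numeric vector of event times in seconds.
#' @param app_label optional character vector of labels carried through
#'   I/O but ignored by all computations.
#' @return An object of class `bb_events`: list with `times` (strictly
#'   increasing), `app_label`, and `n_duplicates_dropped`.
#' @export
bb_events <- function(times, app_label = NULL) {
  times <- as.numeric(times)
  if (anyNA(times) || any(!is.finite(times)))
    stop("event times must be finite numbers")
  ord <- order(times)
  times <- times[ord]
  if (!is.null(app_label)) app_label <- as.character(app_label)[ord]
  dup <- duplicated(times)
  structure(
    list(times = times[!dup],
         app_label = if (is.null(app_label)) NULL else app_label[!dup],
         n_duplicates_dropped = sum(dup)),
    class = "bb_events")
}

#' @export
print.bb_events <- function(x, ...) {
  cat(sprintf("<bb_events> %d event%s", length(x$times),
              if (length(x$times) == 1) "" else "s"))
  if (length(x$times))
    cat(sprintf(" spanning [%.3f, %.3f] s", min(x$times), max(x$times)))
  if (x$n_duplicates_dropped)
    cat(sprintf(" (%d duplicate%s dropped)", x$n_duplicates_dropped,
                if (x$n_duplicates_dropped == 1) "" else "s"))
  cat("\n")
  invisible(x)
}

# normalize numeric vector / bb_events to a sorted numeric vector
as_event_times <- function(events) {
  if (inherits(events, "bb_events")) return(events$times)
  ev <- as.numeric(events)
  if (is.unsorted(ev, strictly = TRUE)) ev <- sort(unique(ev))
  ev
}

#' Read behavioral events from delimited text
#'
#' Expects a CSV with a `time_s` column (header), or headerless text with
#' one timestamp per row. An optional `app_label` column is carried
#' through untouched. Times are sorted; exact duplicates are dropped and
#' counted.
#'
#' @param path file path.
#' @return A [bb_events()] object.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(bb_events(numeric(0)))
  has_header <- grepl("time_s", lines[[1L]], fixed = TRUE)
  if (has_header) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    tvals <- suppressWarnings(as.numeric(df$time_s))
    if (anyNA(tvals)) {
      bad <- which(is.na(tvals))[1L]
      stop("non-numeric `time_s` value at line ", bad + 1L, " of ", path,
           ": '", df$time_s[bad], "'")
    }
    app <- if ("app_label" %in% names(df)) df$app_label else NULL
    return(bb_events(tvals, app))
  }
  tvals <- suppressWarnings(as.numeric(trimws(lines)))
  if (anyNA(tvals)) {
    bad <- which(is.na(tvals))[1L]
    stop("non-numeric timestamp at line ", bad, " of ", path, ": '",
         trimws(lines[bad]), "'")
  }
  bb_events(tvals)
}

#' Write behavioral events as CSV
#' @param events a [bb_events()] or numeric vector of times.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  if (!inherits(events, "bb_events")) events <- bb_events(events)
  df <- data.frame(time_s = events$times)
  if (!is.null(events$app_label)) df$app_label <- events$app_label
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Zero-phase Butterworth filters
#'
#' Convenience preprocessing filters (forward-backward, so zero phase
#' shift). The burst pipeline itself does not require them; they are
#' offered for data that has not been band-limited upstream.
#'
#' @param recording a [bb_recording()].
#' @param cutoff high-pass corner frequency in Hz.
#' @param band length-2 numeric, band-pass corners in Hz.
#' @param order Butterworth order of the one-way design (default 4).
#' @return A filtered [bb_recording()].
#' @export
filter_highpass <- function(recording, cutoff = 0.5, order = 4) {
  stopifnot(inherits(recording, "bb_recording"))
  bf <- signal::butter(order, cutoff / (recording$fs / 2), type = "high")
  recording$signal <- t(apply(recording$signal, 1L, function(x)
    signal::filtfilt(bf, x)))
  recording
}

#' @rdname filter_highpass
#' @export
filter_bandpass <- function(recording, band = c(1, 45), order = 4) {
  stopifnot(inherits(recording, "bb_recording"), length(band) == 2L)
  bf <- signal::butter(order, band / (recording$fs / 2), type = "pass")
  recording$signal <- t(apply(recording$signal, 1L, function(x)
    signal::filtfilt(bf, x)))
  recording
}
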