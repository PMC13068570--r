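# Minimal European Data Format (EDF) I/O: continuous, unannotated,
# 16-bit records, one sampling rate shared by all channels. Covers the
# subset needed to exchange continuous EEG with standard tooling; no
# installed R package provides an EDF reader, hence this one.

edf_pad <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- rawToChar(readBin(con, "raw", 256L))
  field <- function(from, len) trimws(substr(hdr, from, from + len - 1L))
  n_rec <- as.integer(field(237L, 8L))
  rec_dur <- as.numeric(field(245L, 8L))
  ns <- as.integer(field(253L, 4L))
  if (is.na(ns) || ns < 1L) stop("invalid EDF header in ", path)
  sig_hdr <- rawToChar(readBin(con, "raw", 256L * ns))
  sfield <- function(offset, len) {
    vapply(seq_len(ns), function(i)
      trimws(substr(sig_hdr, offset * ns + (i - 1L) * len + 1L,
                    offset * ns + i * len)), "")
  }
  labels <- sfield(0L, 16L)
  # offsets in bytes from start of signal header block
  off <- c(label = 0L, transducer = 16L * ns, dim = 96L * ns,
           pmin = 104L * ns, pmax = 112L * ns, dmin = 120L * ns,
           dmax = 128L * ns, prefilter = 136L * ns, nsamp = 216L * ns)
  getf <- function(byte_off, len) {
    vapply(seq_len(ns), function(i)
      trimws(substr(sig_hdr, byte_off + (i - 1L) * len + 1L,
                    byte_off + i * len)), "")
  }
  pmin <- as.numeric(getf(off["pmin"], 8L))
  pmax <- as.numeric(getf(off["pmax"], 8L))
  dmin <- as.numeric(getf(off["dmin"], 8L))
  dmax <- as.numeric(getf(off["dmax"], 8L))
  nsamp <- as.integer(getf(off["nsamp"], 8L))
  if (length(unique(nsamp)) != 1L)
    stop("EDF with per-channel sampling rates is not supported")
  if (is.na(rec_dur) || rec_dur <= 0) stop("invalid EDF record duration")
  fs <- nsamp[1L] / rec_dur
  sig <- matrix(0, ns, nsamp[1L] * n_rec)
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", ns * nsamp[1L], size = 2L,
                     signed = TRUE, endian = "little")
    cols <- ((r - 1L) * nsamp[1L] + 1L):(r * nsamp[1L])
    sig[, cols] <- matrix(block, nsamp[1L], ns)[, seq_len(ns), drop = FALSE] |> t()
  }
  scale <- (pmax - pmin) / (dmax - dmin)
  sig <- sweep(sweep(sig, 1L, dmin) * scale, 1L, pmin, "+")
  bb_recording(sig, fs = fs, labels = labels)
}

#' Write a recording as a 16-bit EDF file
#'
#' Quantizes each channel to the 16-bit range spanned by its own minimum
#' and maximum; round-trip error is bounded by (max-min)/65534 per
#' channel. The whole signal is stored as one data record.
#'
#' @param recording a [bb_recording()].
#' @param path output `.edf` path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "bb_recording"))
  sig <- recording$signal
  ns <- nrow(sig); n <- ncol(sig)
  pmin <- apply(sig, 1L, min); pmax <- apply(sig, 1L, max)
  flat <- pmax - pmin < .Machine$double.eps
  pmax[flat] <- pmin[flat] + 1
  dmin <- -32767L; dmax <- 32767L
  dig <- round(sweep(sweep(sig, 1L, pmin), 1L,
                     (pmax - pmin) / (dmax - dmin), "/")) + dmin
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8L), edf_pad("", 80L), edf_pad("", 80L),
    edf_pad("01.01.00", 8L), edf_pad("00.00.00", 8L),
    edf_pad(256L * (1L + ns), 8L), edf_pad("", 44L),
    edf_pad(1L, 8L), edf_pad(format(n / recording$fs, digits = 7), 8L),
    edf_pad(ns, 4L))
  writeChar(hdr, con, eos = NULL)
  num8 <- function(v) edf_pad(format(v, digits = 7), 8L)
  blocks <- c(
    paste0(edf_pad(recording$labels, 16L), collapse = ""),
    paste0(rep(edf_pad("", 80L), ns), collapse = ""),
    paste0(rep(edf_pad("uV", 8L), ns), collapse = ""),
    paste0(num8(pmin), collapse = ""),
    paste0(num8(pmax), collapse = ""),
    paste0(rep(edf_pad(dmin, 8L), ns), collapse = ""),
    paste0(rep(edf_pad(dmax, 8L), ns), collapse = ""),
    paste0(rep(edf_pad("", 80L), ns), collapse = ""),
    paste0(rep(edf_pad(n, 8L), ns), collapse = ""),
    paste0(rep(edf_pad("", 32L), ns), collapse = ""))
  writeChar(paste0(blocks, collapse = ""), con, eos = NULL)
  writeBin(as.integer(t(dig)), con, size = 2L, endian = "little")
  invisible(path)
}
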