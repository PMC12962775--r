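# Minimal EDF (European Data Format, 16-bit) reader/writer.
# Covers the standard-header subset this package emits: one continuous
# recording, 1-s data records, identical sampling rate on all channels.

pad <- function(x, n) {
  x <- substr(as.character(x), 1L, n)
  formatC(x, width = n, flag = "-")
}

#' Write a time series to an EDF file
#'
#' Standard EDF with 16-bit samples, 1-second data records and per-channel
#' physical scaling spanning the data range. The sampling rate must be a
#' whole number of samples per second. Trailing samples that do not fill a
#' full record are dropped (EDF stores whole records only).
#'
#' @param ts a [time_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(ts, path) {
  fs <- ts$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF export needs an integer sampling rate")
  fs <- as.integer(round(fs))
  nc <- nrow(ts$samples)
  n_rec <- ncol(ts$samples) %/% fs
  if (n_rec < 1L) stop("signal shorter than one 1-s EDF record")
  x <- ts$samples[, seq_len(n_rec * fs), drop = FALSE]

  pmin_ <- apply(x, 1, min)
  pmax_ <- apply(x, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767
  gain <- (dmax - dmin) / (pmax_ - pmin_)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad("X X X X", 80), pad("Startdate X X X X", 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256 * (1 + nc), 8), pad("", 44),
    pad(n_rec, 8), pad("1", 8), pad(nc, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, w) writeChar(paste(vapply(vals, pad, "", n = w),
                                             collapse = ""), con, eos = NULL)
  field(ts$labels, 16)
  field(rep("", nc), 80)                      # transducer
  field(rep("uV", nc), 8)                     # physical dimension
  field(sprintf("%.8g", pmin_), 8)
  field(sprintf("%.8g", pmax_), 8)
  field(rep(dmin, nc), 8)
  field(rep(dmax, nc), 8)
  field(rep("", nc), 80)                      # prefiltering
  field(rep(fs, nc), 8)                       # samples per record
  field(rep("", nc), 32)                      # reserved

  dig <- round((x - pmin_) * gain + dmin)     # row-wise recycling is exact here
  dig <- pmin(pmax(dig, dmin), dmax)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into a time series
#'
#' Supports continuous 16-bit EDF with a uniform sampling rate across
#' channels, as written by [write_edf()] and standard EEG exporters.
#'
#' @param path EDF file path.
#' @param channels optional character vector of channel labels to keep.
#' @return A [time_series()].
#' @export
read_edf <- function(path, channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                        # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nc <- as.integer(rd(4))
  if (is.na(nc) || nc < 1L) stop("not a parsable EDF header")
  rdv <- function(w) vapply(seq_len(nc), function(i) rd(w), "")
  labels <- rdv(16); rdv(80); rdv(8)
  pmin_ <- as.numeric(rdv(8)); pmax_ <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (length(unique(spr)) != 1L)
    stop("mixed sampling rates across channels are not supported")
  fs <- spr[1] / rec_dur
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  out <- matrix(0, nc, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = nc * spr[1], size = 2, signed = TRUE,
                   endian = "little")
    if (length(raw) < nc * spr[1]) stop("truncated EDF data record")
    block <- matrix(raw, nrow = spr[1])       # samples x channels
    out[, ((r - 1L) * spr[1] + 1L):(r * spr[1])] <-
      t((block - rep(dmin, each = spr[1])) * rep(gain, each = spr[1]) +
          rep(pmin_, each = spr[1]))
  }
  ts <- time_series(out, fs = fs, labels = labels)
  if (!is.null(channels)) ts <- ts[channels]
  ts
}
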