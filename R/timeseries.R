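#' Multichannel time series
#'
#' Container for sampled multichannel signals: a channels-by-samples numeric
#' matrix, a sampling rate in Hz and channel labels. All biomarker functions
#' in the package consume this class.
#'
#' @param samples numeric matrix (channels x samples) or vector (one channel),
#'   amplitudes in microvolts.
#' @param fs sampling rate in Hz, positive scalar.
#' @param labels character vector of channel names; defaults to `ch1, ch2, ...`.
#' @return An object of class `time_series`: a list with elements `samples`
#'   (matrix), `fs`, `labels`.
#' @examples
#' ts <- time_series(sin(2 * pi * 10 * seq(0, 2, by = 1 / 250)), fs = 250)
#' ts
#' @export
time_series <- function(samples, fs, labels = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("`samples` must be a numeric matrix (channels x samples)")
  if (!all(is.finite(samples))) stop("`samples` contains non-finite values")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive finite scalar (Hz)")
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(samples)))
  if (length(labels) != nrow(samples))
    stop("`labels` length must equal the number of channels")
  structure(list(samples = samples, fs = fs, labels = as.character(labels)),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs))
  cat("  channels:", paste(utils::head(x$labels, 8), collapse = ", "),
      if (length(x$labels) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
`[.time_series` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$labels)
  if (anyNA(i)) stop("unknown channel label")
  time_series(x$samples[i, , drop = FALSE], x$fs, x$labels[i])
}

n_samples <- function(ts) ncol(ts$samples)

channel <- function(ts, i = 1L) {
  if (is.character(i)) i <- match(i, ts$labels)
  as.numeric(ts$samples[i, ])
}

#' Write a time series as flat binary with a JSON sidecar
#'
#' Samples are stored as little-endian float64, channel-major; `fs`, labels and
#' dimensions go to `<path>.json`.
#'
#' @param ts a [time_series()].
#' @param path output path for the binary payload (sidecar is `<path>.json`).
#' @return `path`, invisibly.
#' @export
write_flat <- function(ts, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(ts$samples)), con, size = 8, endian = "little")
  meta <- list(fs = ts$fs, labels = ts$labels,
               n_channels = nrow(ts$samples), n_samples = ncol(ts$samples),
               dtype = "float64le", order = "channel-major")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a flat binary + JSON sidecar time series
#'
#' @param path path written by [write_flat()].
#' @param channels optional character vector of channel labels to keep.
#' @return A [time_series()].
#' @export
read_flat <- function(path, channels = NULL) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, what = "numeric", n = meta$n_channels * meta$n_samples,
               size = 8, endian = "little")
  ts <- time_series(matrix(x, nrow = meta$n_channels, byrow = TRUE),
                    fs = meta$fs, labels = meta$labels)
  if (!is.null(channels)) ts <- ts[channels]
  ts
}
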