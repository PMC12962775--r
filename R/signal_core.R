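#' Frequency band
#'
#' @param f_lo,f_hi band edges in Hz, `0 < f_lo < f_hi`.
#' @return An object of class `band`.
#' @export
band <- function(f_lo, f_hi) {
  if (!is.numeric(f_lo) || !is.numeric(f_hi) || f_lo <= 0 || f_hi <= f_lo)
    stop("need 0 < f_lo < f_hi")
  structure(list(f_lo = f_lo, f_hi = f_hi), class = "band")
}

#' The two fixed log-spaced alpha bands
#'
#' Low and high alpha, 8.3-10.5 and 10.5-13.4 Hz; log-spaced edges trade off
#' spectral resolution against filter overlap for DFA work.
#'
#' @return Named list of two [band()] objects (`alpha_lo`, `alpha_hi`).
#' @export
alpha_bands <- function() {
  list(alpha_lo = band(8.3, 10.5), alpha_hi = band(10.5, 13.4))
}

# FFT-based linear convolution with a centered (delay-compensated) FIR kernel.
fir_apply <- function(x, h) {
  n <- length(x); L <- length(h)
  half <- (L - 1L) %/% 2L
  m <- stats::nextn(n + L - 1L, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(m - n))) *
                       stats::fft(c(h, numeric(m - L))), inverse = TRUE)) / m
  y[(half + 1L):(half + n)]
}

#' Zero-phase band-pass filter
#'
#' Linear-phase FIR (Hamming-windowed, ~1 Hz transition width) applied with
#' group-delay compensation, so the output is zero-phase. Samples within one
#' filter half-length of either edge are unreliable; their count is recorded
#' in the `"edge"` attribute and [amplitude_envelope()] trims them.
#'
#' @param ts a [time_series()].
#' @param bd a [band()]; must lie below Nyquist.
#' @param transition transition width in Hz (sets filter length).
#' @return A filtered [time_series()] with attribute `"edge"`.
#' @export
bandpass <- function(ts, bd, transition = 1) {
  stopifnot(inherits(ts, "time_series"), inherits(bd, "band"))
  nyq <- ts$fs / 2
  if (bd$f_hi >= nyq) stop("band upper edge must lie below Nyquist")
  ntaps <- round(3.3 * ts$fs / transition)
  ntaps <- as.integer(ntaps + (1 - ntaps %% 2L))      # odd -> integer delay
  if (ntaps >= n_samples(ts)) stop("signal too short for the filter length")
  h <- signal::fir1(ntaps - 1L, c(bd$f_lo, bd$f_hi) / nyq, type = "pass")
  out <- ts
  out$samples <- t(apply(ts$samples, 1, fir_apply, h = as.numeric(h)))
  if (nrow(ts$samples) == 1L) out$samples <- matrix(out$samples, nrow = 1)
  attr(out, "edge") <- (ntaps - 1L) %/% 2L
  attr(out, "band") <- bd
  out
}

#' Amplitude envelope via the analytic signal
#'
#' Magnitude of the analytic signal (FFT half-spectrum construction) of each
#' channel. Intended for narrow-band inputs; for an AM tone
#' `a(t) sin(2 pi f t)` with slowly varying `a(t) >= 0` it recovers `a(t)`.
#' Filter edge samples recorded by [bandpass()] are trimmed.
#'
#' @param ts a (narrow-band) [time_series()], typically from [bandpass()].
#' @return A [time_series()] of non-negative envelopes (edge-trimmed).
#' @export
amplitude_envelope <- function(ts) {
  stopifnot(inherits(ts, "time_series"))
  edge <- attr(ts, "edge")
  env <- t(apply(ts$samples, 1, function(x) Mod(analytic_signal(x))))
  if (nrow(ts$samples) == 1L) env <- matrix(env, nrow = 1)
  if (!is.null(edge) && edge > 0 && ncol(env) > 2L * edge)
    env <- env[, (edge + 1L):(ncol(env) - edge), drop = FALSE]
  out <- time_series(env, ts$fs, ts$labels)
  attr(out, "band") <- attr(ts, "band")
  out
}

analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  hmul <- numeric(n)
  if (n %% 2L == 0L) {
    hmul[c(1, n / 2 + 1)] <- 1
    hmul[2:(n / 2)] <- 2
  } else {
    hmul[1] <- 1
    hmul[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * hmul, inverse = TRUE) / n
}

#' Signal profile (integrated demeaned envelope)
#'
#' `S(t) = sum_{k<=t} (A(k) - mean(A))`: the cumulative sum of the demeaned
#' amplitude envelope, the common substrate of DFA and the normalized
#' fluctuation function. By construction `S(n) = 0` up to rounding.
#'
#' @param env numeric envelope vector (or single-channel [time_series()]).
#' @return Numeric profile vector of the same length.
#' @export
signal_profile <- function(env) {
  if (inherits(env, "time_series")) env <- channel(env)
  if (length(env) == 0L) stop("empty envelope")
  if (!all(is.finite(env))) stop("envelope contains non-finite values")
  cumsum(env - mean(env))
}

#' Split a signal into overlapping windows
#'
#' Maximal set of fully contained windows of `window_s` seconds with the
#' given fractional overlap; the start step is
#' `round(window_s * fs * (1 - overlap))` samples.
#'
#' @param n_samples signal length in samples.
#' @param fs sampling rate, Hz.
#' @param window_s window length, seconds.
#' @param overlap fractional overlap in `[0, 1)`.
#' @return An object of class `window_set`: list with `starts` (1-based
#'   sample indices), `size` (samples), `window_s`, `overlap`, `fs`.
#' @export
split_windows <- function(n_samples, fs, window_s = 5, overlap = 0.8) {
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)")
  size <- as.integer(round(window_s * fs))
  if (n_samples < size)
    stop(sprintf("signal too short: %d samples < one %g-s window (%d samples)",
                 n_samples, window_s, size))
  step <- max(1L, as.integer(round(size * (1 - overlap))))
  starts <- seq.int(1L, n_samples - size + 1L, by = step)
  structure(list(starts = starts, size = size, window_s = window_s,
                 overlap = overlap, fs = fs, n = length(starts)),
            class = "window_set")
}

# Residual standard deviations after per-window linear detrending.
# seg_mat: size x n_windows matrix of window contents.
detrended_sd <- function(seg_mat) {
  n <- nrow(seg_mat)
  tt <- seq_len(n) - (n + 1) / 2                 # centered regressor
  stt <- sum(tt^2)
  beta <- crossprod(tt, seg_mat) / stt           # 1 x w slopes
  cm <- colMeans(seg_mat)
  resid <- seg_mat - rep(cm, each = n) - outer(tt, as.numeric(beta))
  sqrt(colSums(resid^2) / n)
}

window_matrix <- function(x, ws) {
  idx <- outer(seq_len(ws$size) - 1L, ws$starts, `+`)
  matrix(x[idx], nrow = ws$size)
}

#' Detrended fluctuation analysis
#'
#' Classical DFA-1 of an amplitude envelope: integrate the demeaned envelope
#' ([signal_profile()]), split into log-spaced window sizes, linearly
#' detrend each window, take the root-mean-square residual per window and
#' average across windows; the scaling exponent is the least-squares slope
#' of `log10` fluctuation versus `log10` window size over `fit_range_s`.
#' An exponent of 0.5 indicates an uncorrelated signal; values approaching
#' 1 indicate strong long-range temporal correlations.
#'
#' @param env envelope vector or single-channel [time_series()].
#' @param fs sampling rate, Hz (ignored if `env` is a time series).
#' @param fit_range_s length-2 fit range in seconds (default 2-20 s; keep the
#'   lower bound above a few periods of the band's low edge to avoid
#'   filter-induced correlations).
#' @param n_sizes number of log-spaced window sizes.
#' @param overlap window overlap inside the DFA (default 50%).
#' @return Object of class `dfa_result`: `window_sizes_s`, `fluctuation`,
#'   `exponent`, `fit_range_s`, `r2`.
#' @examples
#' set.seed(1)
#' d <- dfa(abs(rnorm(5000)), fs = 100)
#' d$exponent   # near 0.5 for uncorrelated input
#' @export
dfa <- function(env, fs = NULL, fit_range_s = c(2, 20), n_sizes = 10,
                overlap = 0.5) {
  if (inherits(env, "time_series")) { fs <- env$fs; env <- channel(env) }
  if (is.null(fs)) stop("`fs` required for a bare envelope vector")
  if (stats::sd(env) == 0) stop("zero-variance envelope")
  sizes_s <- exp(seq(log(fit_range_s[1]), log(fit_range_s[2]),
                     length.out = n_sizes))
  sizes <- unique(pmax(4L, as.integer(round(sizes_s * fs))))
  sizes <- sizes[sizes <= length(env) %/% 2L]
  if (length(sizes) < 2L) stop("envelope too short for >= 2 DFA window sizes")
  prof <- signal_profile(env)
  fluct <- vapply(sizes, function(sz) {
    ws <- split_windows(length(prof), fs, sz / fs, overlap)
    mean(detrended_sd(window_matrix(prof, ws)))
  }, 0)
  lx <- log10(sizes / fs); ly <- log10(fluct)
  fit <- stats::lm.fit(cbind(1, lx), ly)
  r2 <- 1 - sum(fit$residuals^2) / sum((ly - mean(ly))^2)
  structure(list(window_sizes_s = sizes / fs, fluctuation = fluct,
                 exponent = unname(fit$coefficients[2]),
                 fit_range_s = fit_range_s, r2 = r2),
            class = "dfa_result")
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf("<dfa_result> exponent = %.3f (r2 = %.3f), %d sizes in %g-%g s\n",
              x$exponent, x$r2, length(x$window_sizes_s),
              x$fit_range_s[1], x$fit_range_s[2]))
  invisible(x)
}
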