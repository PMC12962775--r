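#' Windowed amplitudes and normalized fluctuations
#'
#' The per-window ingredients of fE/I. For each window: the mean amplitude
#' envelope `amp_w`; the signal-profile segment divided by `amp_w`, linearly
#' detrended; and the normalized fluctuation `nF_w`, the standard deviation
#' of that amplitude-normalized, detrended profile segment. Windows with
#' zero mean amplitude are dropped (pairwise) and counted.
#'
#' @param env envelope vector or single-channel [time_series()].
#' @param windows a [split_windows()] window set over `length(env)`.
#' @return List with `window_amplitudes`, `window_nf` (aligned numeric
#'   vectors) and `n_dropped`.
#' @export
normalized_fluctuation <- function(env, windows) {
  if (inherits(env, "time_series")) env <- channel(env)
  stopifnot(inherits(windows, "window_set"))
  if (windows$n < 2L) stop("need at least 2 windows")
  prof <- signal_profile(env)
  envm <- window_matrix(env, windows)
  amp <- colMeans(envm)
  keep <- amp > 0
  segs <- window_matrix(prof, windows)
  segs <- segs[, keep, drop = FALSE] /
    rep(amp[keep], each = windows$size)
  nf <- detrended_sd(segs)
  list(window_amplitudes = amp[keep], window_nf = nf,
       n_dropped = sum(!keep))
}

#' Functional excitation/inhibition ratio (fE/I)
#'
#' Narrow-band criticality biomarker: `fE/I = 1 - r`, where `r` is the
#' Pearson correlation between window mean amplitudes and normalized
#' fluctuations over the set of windows. Values of 1 indicate a critical
#' state, < 1 a subcritical (inhibition-dominated) and > 1 a supercritical
#' (excitation-dominated) regime. Because a signal without long-range
#' temporal correlations cannot exhibit the amplitude-fluctuation
#' covariation the biomarker reads, fE/I is gated on the DFA exponent of
#' the same band's envelope: results with `dfa_exponent <= dfa_gate`
#' (default 0.6) are reported as missing (`valid = FALSE`).
#'
#' @param ts single-channel [time_series()] (raw; filtered internally).
#' @param bd a [band()], e.g. one of [alpha_bands()].
#' @param window_s window length in seconds (default 5).
#' @param overlap fractional window overlap (default 0.8).
#' @param dfa_gate DFA validity threshold (default 0.6; 0.55 supported for
#'   sensitivity analyses).
#' @param dfa_fit_range_s DFA fit range passed to [dfa()].
#' @param min_windows minimum number of usable windows (default 10).
#' @return Object of class `fei_result`: `fei`, `r`, `window_amplitudes`,
#'   `window_nf`, `n_windows`, `dfa_exponent`, `valid`, `reason`, `band`.
#' @examples
#' ts <- generate_signal(signal_params(duration_s = 60, seed = 7))
#' compute_fei(ts, band(8.3, 10.5))
#' @export
compute_fei <- function(ts, bd, window_s = 5, overlap = 0.8, dfa_gate = 0.6,
                        dfa_fit_range_s = c(2, 20), min_windows = 10L) {
  stopifnot(inherits(ts, "time_series"))
  env <- amplitude_envelope(bandpass(ts, bd))
  e <- channel(env)
  d <- dfa(e, env$fs, fit_range_s = dfa_fit_range_s)

  res <- list(fei = NA_real_, r = NA_real_, window_amplitudes = numeric(0),
              window_nf = numeric(0), n_windows = 0L,
              dfa_exponent = d$exponent, valid = FALSE, reason = "",
              band = bd, window_s = window_s, overlap = overlap,
              dfa_gate = dfa_gate)
  class(res) <- "fei_result"

  ws <- tryCatch(split_windows(length(e), env$fs, window_s, overlap),
                 error = function(e) NULL)
  if (is.null(ws)) { res$reason <- "too short"; return(res) }
  nf <- normalized_fluctuation(e, ws)
  res$window_amplitudes <- nf$window_amplitudes
  res$window_nf <- nf$window_nf
  res$n_windows <- length(nf$window_amplitudes)
  if (res$n_windows < min_windows) { res$reason <- "too few windows"; return(res) }
  if (stats::sd(nf$window_amplitudes) == 0 || stats::sd(nf$window_nf) == 0) {
    res$reason <- "zero variance"; return(res)
  }
  r <- stats::cor(nf$window_amplitudes, nf$window_nf)
  if (d$exponent <= dfa_gate) {
    res$reason <- "DFA below gate"
    return(res)                                  # fei stays missing
  }
  res$r <- r
  res$fei <- 1 - r
  res$valid <- TRUE
  res
}

#' @export
print.fei_result <- function(x, ...) {
  if (x$valid)
    cat(sprintf("<fei_result> fE/I = %.3f (r = %.3f), DFA = %.3f, %d windows\n",
                x$fei, x$r, x$dfa_exponent, x$n_windows))
  else
    cat(sprintf("<fei_result> invalid (%s), DFA = %.3f\n",
                x$reason, x$dfa_exponent))
  invisible(x)
}

#' fE/I on the individual alpha band
#'
#' Builds the individualized alpha band `[paf - 2, paf + 2]` Hz around the
#' peak alpha frequency, splits it into two equal half-bands (mirroring the
#' fixed low/high alpha analysis) and computes fE/I on each.
#'
#' @param ts single-channel [time_series()].
#' @param paf peak alpha frequency in Hz (6-14), or `NA` when no alpha peak
#'   was detected.
#' @param ... passed to [compute_fei()].
#' @return Named list of two `fei_result` objects (`iaf_lo`, `iaf_hi`);
#'   both invalid with reason `"no alpha peak"` when `paf` is missing.
#' @export
compute_fei_iaf <- function(ts, paf, ...) {
  if (is.na(paf)) {
    empty <- structure(list(fei = NA_real_, r = NA_real_,
                            window_amplitudes = numeric(0),
                            window_nf = numeric(0), n_windows = 0L,
                            dfa_exponent = NA_real_, valid = FALSE,
                            reason = "no alpha peak", band = NULL),
                       class = "fei_result")
    return(list(iaf_lo = empty, iaf_hi = empty))
  }
  if (paf < 6 || paf > 14) stop("paf must lie in [6, 14] Hz")
  list(iaf_lo = compute_fei(ts, band(paf - 2, paf), ...),
       iaf_hi = compute_fei(ts, band(paf, paf + 2), ...))
}
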