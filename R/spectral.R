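#' Welch power spectral density
#'
#' Averaged periodogram over Hann-tapered, overlapping, demeaned segments;
#' one-sided density normalized so that `sum(psd) * df` equals the signal
#' variance. Frequency resolution is `1/seg_s`.
#'
#' @param ts single-channel [time_series()] (or numeric vector with `fs`).
#' @param seg_s segment length in seconds (default 4, i.e. 0.25 Hz bins).
#' @param overlap fractional segment overlap (default 0.5).
#' @param fs sampling rate when `ts` is a bare vector.
#' @return List with `freqs` (Hz, excludes DC) and `psd`.
#' @export
welch_psd <- function(ts, seg_s = 4, overlap = 0.5, fs = NULL) {
  if (inherits(ts, "time_series")) { fs <- ts$fs; x <- channel(ts) }
  else x <- as.numeric(ts)
  if (is.null(fs)) stop("`fs` required")
  nseg <- as.integer(round(seg_s * fs))
  if (length(x) < 2L * nseg) stop("signal too short for two Welch segments")
  step <- max(1L, as.integer(round(nseg * (1 - overlap))))
  starts <- seq.int(1L, length(x) - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))   # Hann
  u <- sum(w^2)
  nf <- nseg %/% 2L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg))[2:(nf + 1L)]^2
    acc <- acc + p
  }
  psd <- acc / length(starts) * 2 / (fs * u)
  if (nseg %% 2L == 0L) psd[nf] <- psd[nf] / 2          # Nyquist not doubled
  list(freqs = (1:nf) * fs / nseg, psd = psd)
}

gaussian_peaks <- function(f, pars) {
  # pars: matrix with columns center, height, sd
  if (is.null(pars) || nrow(pars) == 0L) return(numeric(length(f)))
  rowSums(vapply(seq_len(nrow(pars)), function(i)
    pars[i, 2] * exp(-(f - pars[i, 1])^2 / (2 * pars[i, 3]^2)),
    numeric(length(f))))
}

# Robust aperiodic fit in log10-log10 space: OLS, then refit on the points at
# or below the initial line (peak regions push residuals positive and are
# thereby excluded). Returns c(offset, beta) for log10 P = offset - beta*log10 f.
fit_aperiodic_robust <- function(lf, lp) {
  co <- stats::lm.fit(cbind(1, lf), lp)$coefficients
  resid <- lp - (co[1] + co[2] * lf)
  thresh <- stats::quantile(pmax(resid, 0), 0.025)
  keep <- pmax(resid, 0) <= thresh
  if (sum(keep) >= 3L) co <- stats::lm.fit(cbind(1, lf[keep]), lp[keep])$coefficients
  c(offset = unname(co[1]), beta = unname(-co[2]))
}

#' Spectral parameterization (aperiodic + periodic decomposition)
#'
#' Decomposes a log10 power spectrum into an aperiodic component
#' `offset - beta * log10(f)` (fixed mode, no knee) plus up to `max_n_peaks`
#' Gaussian peaks on the flattened spectrum. The procedure: robust aperiodic
#' fit; iterative extraction of the largest residual peak above
#' `min_peak_height` (log10 units) with widths constrained to
#' `peak_width_limits` (Hz, full width); joint refinement of all peaks; and
#' an aperiodic refit on the peak-removed spectrum.
#'
#' @param freqs,psd PSD as from [welch_psd()]; strictly positive `psd`.
#' @param fit_range length-2 frequency range in Hz.
#' @param max_n_peaks maximum number of Gaussian peaks (default 6).
#' @param peak_width_limits allowed full peak widths in Hz (default c(2, 12)).
#' @param min_peak_height minimum modeled peak height in log10 power
#'   (default 0.1).
#' @return Object of class `spectral_fit`: `freqs`, `psd`, `offset`, `beta`,
#'   `peaks` (data frame center/height/width), `fit_range`, `r2`, plus
#'   `paf`/`peak_height` (filled by [fit_periodic_broadband()]).
#' @export
fit_specparam <- function(freqs, psd, fit_range,
                          max_n_peaks = 6L, peak_width_limits = c(2, 12),
                          min_peak_height = 0.1) {
  sel <- freqs >= fit_range[1] & freqs <= fit_range[2]
  f <- freqs[sel]; p <- psd[sel]
  if (length(f) < 5L) stop("PSD does not cover the fit range")
  if (any(p <= 0)) stop("non-positive PSD values in the fit range")
  lf <- log10(f); lp <- log10(p)
  ap <- fit_aperiodic_robust(lf, lp)

  sd_lim <- peak_width_limits / 2                    # Gaussian sd bounds, Hz
  flat <- lp - (ap[1] - ap[2] * lf)
  guesses <- NULL
  work <- flat
  for (k in seq_len(max_n_peaks)) {
    i <- which.max(work)
    h <- work[i]
    if (h < min_peak_height) break
    half <- h / 2
    li <- i; while (li > 1L && work[li] > half) li <- li - 1L
    ri <- i; while (ri < length(work) && work[ri] > half) ri <- ri + 1L
    fwhm <- max(f[ri] - f[li], diff(fit_range) / length(f))
    sdg <- min(max(fwhm / 2.355, sd_lim[1]), sd_lim[2])
    guesses <- rbind(guesses, c(f[i], h, sdg))
    work <- work - gaussian_peaks(f, matrix(c(f[i], h, sdg), 1))
  }

  if (!is.null(guesses)) {
    npk <- nrow(guesses)
    obj <- function(th) {
      pars <- matrix(th, ncol = 3)
      sum((flat - gaussian_peaks(f, pars))^2)
    }
    lo <- c(rep(fit_range[1] - peak_width_limits[2], npk), rep(0, npk),
            rep(sd_lim[1], npk))
    hi <- c(rep(fit_range[2] + peak_width_limits[2], npk), rep(Inf, npk),
            rep(sd_lim[2], npk))
    opt <- stats::optim(as.numeric(guesses), obj, method = "L-BFGS-B",
                        lower = lo, upper = hi,
                        control = list(maxit = 200))
    guesses <- matrix(opt$par, ncol = 3)
    guesses <- guesses[guesses[, 2] >= min_peak_height, , drop = FALSE]
    if (nrow(guesses) == 0L) guesses <- NULL
  }

  # refit aperiodic on the peak-removed spectrum
  lp_clean <- lp - gaussian_peaks(f, guesses)
  co <- stats::lm.fit(cbind(1, lf), lp_clean)$coefficients
  ap <- c(offset = unname(co[1]), beta = unname(-co[2]))
  model <- (ap[1] - ap[2] * lf) + gaussian_peaks(f, guesses)
  r2 <- 1 - sum((lp - model)^2) / sum((lp - mean(lp))^2)

  peaks <- if (is.null(guesses)) {
    data.frame(center = numeric(0), height = numeric(0), width = numeric(0))
  } else {
    data.frame(center = guesses[, 1], height = guesses[, 2],
               width = 2.355 * guesses[, 3])
  }
  structure(list(freqs = f, psd = p, offset = unname(ap[1]),
                 beta = unname(ap[2]), peaks = peaks, fit_range = fit_range,
                 r2 = r2, paf = NA_real_, peak_height = NA_real_),
            class = "spectral_fit")
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat(sprintf("<spectral_fit> beta = %.3f, offset = %.3f, %d peak(s), r2 = %.3f\n",
              x$beta, x$offset, nrow(x$peaks), x$r2))
  if (!is.na(x$paf))
    cat(sprintf("  PAF = %.2f Hz (height %.3f log10)\n", x$paf, x$peak_height))
  invisible(x)
}

#' Low-frequency aperiodic (1/f) exponent
#'
#' Fits the aperiodic exponent beta between 1 and 5 Hz — below the alpha
#' peak, the regime where 1/f scaling is most sensitive to E/I balance —
#' with peak settings `peak_width_limits = c(2, 12)`, `max_n_peaks = 6`,
#' `min_peak_height = 0.1`.
#'
#' @param freqs,psd PSD covering 1-5 Hz.
#' @param fit_range fit range in Hz (default `c(1, 5)`).
#' @return A `spectral_fit` (see [fit_specparam()]).
#' @export
fit_aperiodic_lowfreq <- function(freqs, psd, fit_range = c(1, 5)) {
  fit_specparam(freqs, psd, fit_range)
}

#' Broadband periodic fit and peak alpha frequency
#'
#' Decomposes the 1-40 Hz spectrum and defines the peak alpha frequency
#' (PAF) as the center of the largest-height modeled peak between 6 and
#' 14 Hz; `peak_height` is its modeled height above the aperiodic fit in
#' log10 power. Both are missing when no such peak is detected.
#'
#' @param freqs,psd PSD covering 1-40 Hz.
#' @param fit_range fit range in Hz (default `c(1, 40)`).
#' @param paf_range PAF search range (default `c(6, 14)`).
#' @return A `spectral_fit` with `paf` and `peak_height` filled.
#' @export
fit_periodic_broadband <- function(freqs, psd, fit_range = c(1, 40),
                                   paf_range = c(6, 14)) {
  fit <- fit_specparam(freqs, psd, fit_range)
  pk <- fit$peaks[fit$peaks$center >= paf_range[1] &
                    fit$peaks$center <= paf_range[2], , drop = FALSE]
  if (nrow(pk) > 0L) {
    best <- which.max(pk$height)
    fit$paf <- pk$center[best]
    fit$peak_height <- pk$height[best]
  }
  fit
}

#' Individual alpha band from the peak alpha frequency
#'
#' Symmetric +/- 2 Hz expansion around the PAF, preventing excessively
#' narrow or broad individualized bands.
#'
#' @param paf peak alpha frequency in Hz, or `NA`.
#' @return A [band()] `[paf - 2, paf + 2]`, or `NULL` when `paf` is missing.
#' @export
make_iaf_band <- function(paf) {
  if (is.na(paf)) return(NULL)
  band(paf - 2, paf + 2)
}
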