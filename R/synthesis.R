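#' Parameters for synthetic alpha-oscillation signals
#'
#' Describes one synthetic EEG channel: a narrow-band alpha carrier whose
#' amplitude envelope is a long-memory (fractional Gaussian noise driven)
#' process with target Hurst/DFA exponent `hurst`, riding on a `1/f^beta`
#' background. `coupling` (kappa) injects a level-dependent gain on
#' within-window envelope fluctuations, so the expected sign of the
#' correlation between window amplitude and normalized fluctuation — hence
#' whether fE/I falls below or above 1 — equals `sign(coupling)`.
#'
#' @param duration_s signal length in seconds.
#' @param fs sampling rate, Hz; `duration_s * fs` must be whole.
#' @param f_alpha carrier frequency, Hz.
#' @param hurst target envelope DFA exponent, in (0, 1).
#' @param coupling amplitude-fluctuation coupling kappa, in \[-1, 1\].
#' @param beta_aperiodic background spectral exponent (power ~ f^-beta), >= 0.
#' @param osc_snr oscillation-to-background RMS amplitude ratio, > 0.
#' @param seed integer seed; identical parameters + seed reproduce the signal
#'   bit for bit.
#' @return An object of class `signal_params`.
#' @export
signal_params <- function(duration_s = 194, fs = 250, f_alpha = 10,
                          hurst = 0.75, coupling = 0, beta_aperiodic = 1.46,
                          osc_snr = 1, seed = 1L) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("`%s` must be a finite numeric scalar", nm))
    x
  }
  duration_s <- num1(duration_s, "duration_s"); fs <- num1(fs, "fs")
  f_alpha <- num1(f_alpha, "f_alpha"); hurst <- num1(hurst, "hurst")
  coupling <- num1(coupling, "coupling")
  beta_aperiodic <- num1(beta_aperiodic, "beta_aperiodic")
  osc_snr <- num1(osc_snr, "osc_snr")
  n <- duration_s * fs
  if (abs(n - round(n)) > 1e-9) stop("duration_s * fs must be an integer")
  if (hurst <= 0 || hurst >= 1) stop("hurst must lie in (0, 1)")
  if (abs(coupling) > 1) stop("coupling must lie in [-1, 1]")
  if (beta_aperiodic < 0) stop("beta_aperiodic must be >= 0")
  if (osc_snr <= 0) stop("osc_snr must be > 0 (envelope undefined otherwise)")
  if (f_alpha <= 0 || f_alpha >= fs / 2) stop("f_alpha must lie in (0, fs/2)")
  structure(list(duration_s = duration_s, fs = fs, f_alpha = f_alpha,
                 hurst = hurst, coupling = coupling,
                 beta_aperiodic = beta_aperiodic, osc_snr = osc_snr,
                 seed = as.integer(seed)),
            class = "signal_params")
}

# Exact fractional Gaussian noise by circulant embedding (Davies-Harte).
# Returns n samples with unit variance and Hurst exponent H; the DFA
# exponent of the sample path equals H in expectation.
fgn_sim <- function(n, H) {
  m <- 2L * (n - 1L)
  k <- 0:(n - 1L)
  g <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  ev <- Re(stats::fft(c(g, g[(n - 1L):2])))
  ev[ev < 0] <- 0                      # guard tiny negative rounding
  w <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m)) / sqrt(2)
  sqrt(2) * Re(stats::fft(sqrt(ev) * w))[seq_len(n)] / sqrt(m)
}

# Brick-wall FFT low-pass; keeps the slow modulation content of the
# envelope process so the modulated carrier stays narrow-band.
lowpass_fft <- function(x, fs, f_cut) {
  n <- length(x)
  X <- stats::fft(x)
  f <- c(0, seq_len(n - 1L)) * fs / n
  f <- pmin(f, fs - f)                 # two-sided frequency axis
  X[f > f_cut] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

# Gaussian noise with power spectral density proportional to f^(-beta),
# built by spectral shaping of white noise; unit standard deviation.
powerlaw_noise <- function(n, beta) {
  if (beta == 0) return(stats::rnorm(n))
  nf <- n %/% 2L
  f <- seq_len(nf) / n                  # positive frequency bins (cycles/sample)
  amp <- f^(-beta / 2)
  pos <- complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf)) * amp
  if (n %% 2L == 0L) pos[nf] <- complex(real = Re(pos[nf]) * sqrt(2), imaginary = 0)
  spec <- c(0 + 0i, pos,
            Conj(rev(pos[seq_len(nf - (1 - n %% 2L))])))
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  as.numeric(scale(x))
}

#' Generate a synthetic alpha-band EEG channel
#'
#' One channel of `duration_s * fs` samples: an alpha carrier at `f_alpha`
#' amplitude-modulated by a log-normal long-memory envelope
#' `exp(sigma * z)` with `z` fractional Gaussian noise of Hurst exponent
#' `hurst`, plus additive `1/f^beta` background scaled to RMS `1/osc_snr`
#' relative to the oscillation. The multiplicative envelope makes
#' within-window fluctuations proportional to window amplitude, so at
#' `coupling = 0` the amplitude-normalized fluctuation function is
#' uncorrelated with amplitude and the downstream fE/I is 1 in expectation.
#' Nonzero `coupling` applies the gain `1 + coupling * z_w` (`z_w` the
#' standardized 5-s block mean amplitude) to detrended within-block envelope
#' fluctuations, tilting that correlation to `sign(coupling)`.
#'
#' @param p a [signal_params()].
#' @return A single-channel [time_series()] with attribute `"envelope"`
#'   holding the generating envelope (useful for oracle tests).
#' @examples
#' ts <- generate_signal(signal_params(duration_s = 20, seed = 42))
#' ts
#' @export
generate_signal <- function(p) {
  stopifnot(inherits(p, "signal_params"))
  n <- as.integer(round(p$duration_s * p$fs))
  set.seed(p$seed)
  # Amplitude modulation is slow relative to the carrier: the long-memory
  # process is low-passed at 3 Hz so the oscillation stays strictly inside
  # f_alpha +/- 3 Hz (no leakage into the 1-5 Hz aperiodic fit range); the
  # DFA scales of interest (>= 2 s, < 0.5 Hz) are untouched. Modulation
  # depth 0.15 keeps the arithmetic-window-mean (Jensen) bias of the
  # log-normal envelope inside Monte-Carlo tolerance of the fE/I = 1
  # zero-coupling contract.
  z <- lowpass_fft(fgn_sim(n, p$hurst), p$fs, 3)
  z <- z / stats::sd(z)
  env <- exp(0.15 * z)

  if (p$coupling != 0) {
    block <- as.integer(round(5 * p$fs))
    starts <- seq(1L, n - block + 1L, by = block)
    bm <- vapply(starts, function(s) mean(env[s:(s + block - 1L)]), 0)
    zw <- as.numeric(scale(bm))
    tt <- seq_len(block)
    for (i in seq_along(starts)) {
      idx <- starts[i]:(starts[i] + block - 1L)
      tr <- stats::fitted(stats::lm.fit(cbind(1, tt), env[idx]))
      gain <- max(1 + p$coupling * zw[i], 0.05)
      env[idx] <- tr + gain * (env[idx] - tr)
    }
    env <- pmax(env, 1e-6)
  }

  phase <- stats::runif(1, 0, 2 * pi)
  osc <- env * sin(2 * pi * p$f_alpha * (seq_len(n) - 1L) / p$fs + phase)
  osc <- osc / stats::sd(osc)
  bg <- powerlaw_noise(n, p$beta_aperiodic) / p$osc_snr
  out <- time_series(10 * (osc + bg), fs = p$fs, labels = "synth")
  attr(out, "envelope") <- env
  out
}

#' Generate pure 1/f^beta background noise
#'
#' Gaussian noise whose expected power spectral density is proportional to
#' `f^(-beta)`; the workhorse behind aperiodic-exponent recovery tests.
#'
#' @param duration_s length in seconds.
#' @param fs sampling rate, Hz.
#' @param beta spectral exponent, >= 0 (0 gives white noise).
#' @param seed integer seed.
#' @return A single-channel [time_series()].
#' @export
generate_aperiodic <- function(duration_s, fs, beta, seed = 1L) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta < 0)
    stop("`beta` must be a finite scalar >= 0")
  n <- as.integer(round(duration_s * fs))
  set.seed(as.integer(seed))
  time_series(10 * powerlaw_noise(n, beta), fs = fs, labels = "aperiodic")
}
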