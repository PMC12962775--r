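make_tone <- function(f, dur = 20, fs = 250, amp = 1) {
  time_series(amp * sin(2 * pi * f * seq(0, dur - 1 / fs, by = 1 / fs)), fs)
}

test_that("bandpass keeps in-band tones and rejects out-of-band tones", {
  bd <- band(8.3, 10.5)
  y <- bandpass(make_tone(10), bd)
  edge <- attr(y, "edge")
  core <- channel(y)[(edge + 1):(ncol(y$samples) - edge)]
  expect_lt(abs(max(abs(core)) - 1), 0.05)

  y2 <- bandpass(make_tone(20), bd)
  core2 <- channel(y2)[(edge + 1):(ncol(y2$samples) - edge)]
  expect_lt(max(abs(core2)), 0.1)

  expect_error(bandpass(make_tone(10), band(100, 130)), "Nyquist")
})

test_that("bandpass preserves the Parseval band-power fraction of white noise", {
  set.seed(42)
  ts <- time_series(rnorm(60 * 250), 250)
  bd <- band(8.3, 10.5)
  y <- bandpass(ts, bd)
  edge <- attr(y, "edge")
  core <- channel(y)[(edge + 1):(60 * 250 - edge)]
  expected <- var(channel(ts)) * (bd$f_hi - bd$f_lo) / 125
  expect_lt(abs(var(core) / expected - 1), 0.2)
})

test_that("amplitude envelope recovers AM modulation", {
  fs <- 250; t <- seq(0, 40 - 1 / fs, by = 1 / fs)
  # constant-amplitude tone
  e1 <- channel(amplitude_envelope(time_series(0.7 * sin(2 * pi * 10 * t), fs)))
  core <- e1[500:(length(e1) - 500)]
  expect_lt(max(abs(core - 0.7)) / 0.7, 0.01)
  # AM identity
  a <- 1 + 0.5 * sin(2 * pi * 0.2 * t)
  e2 <- channel(amplitude_envelope(time_series(a * sin(2 * pi * 10 * t), fs)))
  core_idx <- 500:(length(e2) - 500)
  expect_lt(max(abs(e2[core_idx] - a[core_idx])), 0.05)
})

test_that("envelope is invariant to sign flip of the input", {
  ts <- generate_signal(signal_params(duration_s = 20, seed = 2))
  bd <- band(8.3, 10.5)
  e1 <- amplitude_envelope(bandpass(ts, bd))
  ts$samples <- -ts$samples
  e2 <- amplitude_envelope(bandpass(ts, bd))
  expect_equal(e1$samples, e2$samples, tolerance = 1e-10)
})

test_that("signal profile is the integrated demeaned envelope", {
  expect_equal(signal_profile(c(1, 2, 3)), c(-1, -1, 0))
  expect_equal(signal_profile(rep(2.5, 100)), rep(0, 100))
  set.seed(1)
  a <- abs(rnorm(5000))
  s <- signal_profile(a)
  expect_lt(abs(s[length(s)]), 1e-9 * length(a) * max(a))
  expect_error(signal_profile(numeric(0)), "empty")
})

test_that("split_windows implements the maximal-coverage count formula", {
  ws <- split_windows(2000, 100, 5, 0.8)
  expect_equal(ws$n, 16L)
  expect_equal(ws$starts, seq(1L, 1501L, by = 100L))

  expect_equal(split_windows(500, 100, 5, 0.8)$n, 1L)
  expect_equal(split_windows(2000, 100, 5, 0)$n, 4L)
  expect_error(split_windows(499, 100, 5, 0.8), "too short")

  # property grid: floor((n - size)/step) + 1
  for (n in c(1000, 1537, 4096)) for (w in c(3, 5)) for (ov in c(0, 0.5, 0.8)) {
    ws <- split_windows(n, 100, w, ov)
    size <- round(w * 100); step <- max(1, round(size * (1 - ov)))
    expect_equal(ws$n, floor((n - size) / step) + 1)
    expect_true(max(ws$starts) + size - 1 <= n)
  }
})

test_that("DFA matches the explicit-loop reference to 1e-10", {
  set.seed(7)
  env <- abs(rnorm(2500)) + 0.5
  d <- dfa(env, fs = 250, fit_range_s = c(0.2, 2), n_sizes = 6)
  sizes <- as.integer(round(d$window_sizes_s * 250))
  expect_equal(d$fluctuation, oracle_dfa_fluct(env, 250, sizes),
               tolerance = 1e-10)
  lx <- log10(sizes / 250); ly <- log10(d$fluctuation)
  expect_equal(d$exponent, unname(stats::coef(stats::lm(ly ~ lx))[2]),
               tolerance = 1e-10)
})

test_that("DFA calibration: uncorrelated envelopes scale as 0.5", {
  ex <- vapply(1:10, function(s) {
    set.seed(s); dfa(abs(rnorm(75000)), fs = 250)$exponent
  }, 0)
  expect_lt(abs(mean(ex) - 0.5), 0.05)
})

test_that("DFA is amplitude-scale invariant and monotone in H", {
  set.seed(3)
  env <- abs(rnorm(20000)) + 0.2
  e1 <- dfa(env, 250)$exponent
  e2 <- dfa(37.5 * env, 250)$exponent
  expect_equal(e1, e2, tolerance = 1e-12)

  ms <- vapply(c(0.6, 0.7, 0.8), function(H) {
    mean(vapply(1:6, function(s) {
      set.seed(s); dfa(critEEG:::fgn_sim(40000, H), 250)$exponent
    }, 0))
  }, 0)
  expect_true(all(diff(ms) > 0))
})

test_that("DFA rejects unusable inputs", {
  expect_error(dfa(rep(1, 5000), 250), "zero-variance")
  expect_error(dfa(abs(rnorm(300)), 250, fit_range_s = c(2, 20)), "short")
})
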