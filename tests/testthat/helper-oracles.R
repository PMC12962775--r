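# Independent brute-force oracles: explicit loops, stats:: primitives only.
# These deliberately do not share code with the package internals.

# DFA fluctuation by literal looping: profile, overlapping windows,
# per-window lm() detrend, RMS, mean across windows.
oracle_dfa_fluct <- function(env, fs, sizes, overlap = 0.5) {
  prof <- cumsum(env - mean(env))
  vapply(sizes, function(sz) {
    step <- max(1L, as.integer(round(sz * (1 - overlap))))
    starts <- seq.int(1L, length(prof) - sz + 1L, by = step)
    f <- numeric(length(starts))
    for (i in seq_along(starts)) {
      seg <- prof[starts[i]:(starts[i] + sz - 1L)]
      tt <- seq_along(seg)
      res <- stats::residuals(stats::lm(seg ~ tt))
      f[i] <- sqrt(mean(res^2))
    }
    mean(f)
  }, 0)
}

# Normalized fluctuation following the numbered recipe literally.
oracle_nf <- function(env, fs, window_s = 5, overlap = 0.8) {
  prof <- cumsum(env - mean(env))
  sz <- as.integer(round(window_s * fs))
  step <- max(1L, as.integer(round(sz * (1 - overlap))))
  starts <- seq.int(1L, length(env) - sz + 1L, by = step)
  amp <- nf <- numeric(length(starts))
  for (i in seq_along(starts)) {
    idx <- starts[i]:(starts[i] + sz - 1L)
    amp[i] <- mean(env[idx])
    seg <- prof[idx] / amp[i]
    tt <- seq_along(seg)
    res <- stats::residuals(stats::lm(seg ~ tt))
    nf[i] <- sqrt(mean(res^2))
  }
  list(amp = amp, nf = nf)
}

# Exact rank-sum null distribution by enumerating group assignments.
oracle_wilcoxon_exact_p <- function(x, y) {
  pool <- c(x, y)
  n <- length(x)
  ranks <- rank(pool)
  w_obs <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(length(pool), n)
  w_all <- apply(combs, 2, function(idx) sum(ranks[idx]) - n * (n + 1) / 2)
  mean(abs(w_all - mean(w_all)) >= abs(w_obs - mean(w_all)))
}

# ANOVA/REML variance components for a balanced design with orthogonal
# between- and within-subject fixed effects, via explicit projections.
oracle_balanced_varcomp <- function(value, subject, Xb, Xw) {
  g <- nlevels(subject)
  n <- length(value) / g
  sub_means <- tapply(value, subject, mean)
  # between: subject means on between design (NULL = intercept only)
  fitb <- if (is.null(Xb)) stats::lm(sub_means ~ 1) else stats::lm(sub_means ~ Xb)
  msb <- sum(stats::residuals(fitb)^2) / stats::df.residual(fitb) * n
  # within: deviations from subject means on within design
  dev <- value - sub_means[subject]
  fitw <- stats::lm(dev ~ Xw)
  ssw <- sum(stats::residuals(fitw)^2)
  dfw <- length(value) - g - qr(cbind(1, Xw))$rank + 1
  mse <- ssw / dfw
  list(sigma_e2 = mse, sigma_a2 = max(0, (msb - mse) / n))
}

# small synthetic cohort shortcut used across model tests
make_cohort_table <- function(n = 32, eff = 0, seed = 1, bands = NULL,
                              subject_sd = 0.1, resid_sd = 0.1,
                              level = c("hierarchy", "network")) {
  level <- match.arg(level)
  co <- generate_cohort(cohort_params(n_subjects = n,
                                      effect_interaction = eff,
                                      subject_sd = subject_sd,
                                      resid_sd = resid_sd, seed = seed),
                        bands = bands)
  if (level == "hierarchy") collapse_hierarchy(co$table) else co$table
}
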