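test_that("region OLS recovers an injected IQ slope and flags collinearity", {
  # build per-subject data with known standardized slope
  make_tab <- function(beta_std, n = 128, seed = 1) {
    set.seed(seed)
    iq <- rnorm(n, 111, 13)
    value <- 1.46 + beta_std * 0.3 / 13 * (iq - 111) + rnorm(n, 0, 0.3)
    data.frame(subject_id = sprintf("S%03d", 1:n), age = runif(n, 6, 19),
               sex = sample(c("F", "M"), n, TRUE), iq = iq,
               hierarchy = "association", hemisphere = "L", band = "none",
               value = value)
  }
  est <- vapply(1:20, function(s)
    fit_region_linear(make_tab(-0.19, seed = s))$beta_std, 0)
  expect_lt(abs(mean(est) + 0.19), 0.1)

  null_p <- vapply(1:30, function(s) {
    f <- fit_region_linear(make_tab(0, seed = 100 + s))
    f$terms$p[f$terms$term == "iq"]
  }, 0)
  expect_gte(mean(null_p > 0.05), 0.8)

  bad <- make_tab(0); bad$age <- bad$iq
  expect_error(fit_region_linear(bad), "collinear|rank")
})

test_that("multilevel fit collapses to OLS when the subject variance is zero", {
  tab <- make_cohort_table(n = 40, eff = 0.002, seed = 2, subject_sd = 0)
  m <- fit_multilevel(tab)
  expect_lt(m$ranef_var, 1e-6)
  d <- critEEG:::prep_model_frame(tab)
  d$mod_ <- d$hier
  ols <- stats::lm(value ~ age_c + sex + hemisphere + mod_ * iq_c, data = d)
  expect_equal(m$terms$estimate, unname(stats::coef(ols)), tolerance = 1e-6)
})

test_that("multilevel variance components match balanced ANOVA closed form", {
  # fully balanced within-subject design (constant IQ: the interaction
  # columns vanish), where REML equals the ANOVA estimators exactly
  set.seed(9)
  g <- 24
  subj <- rep(sprintf("S%02d", 1:g), each = 4)
  hier <- rep(c("sensorimotor", "sensorimotor", "association", "association"),
              g)
  hemi <- rep(c("L", "R"), 2 * g)
  val <- rnorm(g, 0, 0.3)[match(subj, unique(subj))] + rnorm(4 * g, 1.4, 0.2)
  tab <- data.frame(subject_id = subj, age = 10, sex = "F", iq = 110,
                    hierarchy = hier, hemisphere = hemi, band = "none",
                    value = val)
  m <- suppressWarnings(suppressMessages(fit_multilevel(tab)))
  Xw <- cbind(hier == "association", hemi == "R") + 0
  o <- oracle_balanced_varcomp(val, factor(subj), NULL, Xw)
  vc <- as.data.frame(lme4::VarCorr(m$fit))
  expect_equal(vc$vcov[vc$grp == "Residual"], o$sigma_e2, tolerance = 1e-6)
  expect_equal(m$ranef_var, o$sigma_a2, tolerance = 1e-6)
})

test_that("multilevel model recovers the injected hierarchy interaction", {
  # collapsing ranks {1,2,3} vs {4,5,6,7} turns the rank-by-IQ slope eff
  # into a hierarchy contrast of 3.5 * eff per IQ point
  eff <- 0.002
  est <- vapply(1:25, function(s) {
    tab <- make_cohort_table(n = 128, eff = eff, seed = 300 + s)
    m <- fit_multilevel(tab)
    m$terms$estimate[m$terms$term == "mod_association:iq_c"]
  }, 0)
  expect_lt(abs(mean(est) / (3.5 * eff) - 1), 0.3)
  m <- fit_multilevel(make_cohort_table(n = 64, eff = eff, seed = 1))
  expect_identical(m$df_method, "satterthwaite")
})

test_that("Johnson-Neyman agrees with brute-force recentering", {
  tab <- make_cohort_table(n = 48, eff = 0.003, seed = 6)
  m <- fit_multilevel(tab)
  jn <- johnson_neyman(m, "mod_association", "iq_c",
                       grid = c(-15, -5, 0, 5, 15))
  d <- critEEG:::prep_model_frame(tab)
  for (i in seq_len(5)) {
    m0 <- jn$grid$moderator[i]
    d$iq_s <- d$iq_c - m0
    ref <- lmerTest::lmer(value ~ age_c + sex + hemisphere +
                            hier * iq_s + (1 | subject_id), data = d)
    co <- stats::coef(summary(ref))["hierassociation", ]
    expect_equal(jn$grid$slope[i], unname(co["Estimate"]), tolerance = 1e-6)
    expect_equal(jn$grid$se[i], unname(co["Std. Error"]), tolerance = 1e-4)
  }
  expect_error(johnson_neyman(m, "sexM", "age_c"), "interaction")
})

test_that("Johnson-Neyman degenerate cases behave", {
  set.seed(2)
  n <- 200
  x <- rnorm(n); mz <- rnorm(n)
  # strong main effect, zero interaction: significant on the whole grid
  y <- 2 * x + rnorm(n)
  fit <- stats::lm(y ~ x * mz)
  jn <- johnson_neyman(fit, "x", "mz")
  expect_true(all(jn$grid$significant))
  # nothing at all: mostly nowhere significant across replicates
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    x <- rnorm(n); mz <- rnorm(n); y <- rnorm(n)
    mean(johnson_neyman(stats::lm(y ~ x * mz), "x", "mz")$grid$significant)
  }, 0)
  expect_gte(mean(hits < 0.5), 0.95)
})

test_that("GAMM shrinks the smooth when the truth is linear", {
  wins <- vapply(1:10, function(s) {
    tab <- make_cohort_table(n = 48, eff = 0.004, seed = 500 + s)
    g <- fit_gamm(tab, "exp1f", "hierarchy")
    sm <- g$smooth[!grepl("subject", g$smooth$term), ]
    all(sm$edf < 1.5)
  }, TRUE)
  expect_gte(mean(wins), 0.8)
  # and the linear interaction is still detected
  ps <- vapply(1:10, function(s) {
    tab <- make_cohort_table(n = 48, eff = 0.004, seed = 500 + s)
    g <- fit_gamm(tab, "exp1f", "hierarchy")
    g$parametric$p[g$parametric$term == "hierassociation:iq_c"]
  }, 0)
  expect_gte(mean(ps < 0.05), 0.8)
})

test_that("GAMM with zero subject variance matches a plain penalized GAM", {
  tab <- make_cohort_table(n = 32, eff = 0.002, seed = 4, subject_sd = 0)
  g <- fit_gamm(tab, "exp1f", "hierarchy")
  d <- g$data
  plain <- mgcv::gam(value ~ sex + hemisphere + age_c + hier * iq_c +
                       ti(iq, by = hier, k = 5),
                     data = d, method = "REML", select = TRUE)
  pr1 <- mgcv::predict.gam(g$fit, exclude = "s(subject_id)")
  pr2 <- predict(plain)
  expect_lt(max(abs(pr1 - pr2)), 1e-1 * stats::sd(d$value))
  # network-level model also runs and reports the effect family size
  gn <- fit_gamm(make_cohort_table(n = 24, seed = 5, level = "network"),
                 "exp1f", "network")
  expect_gt(gn$m_effects, 3)
})

test_that("Bonferroni adjustment is exact, capped, monotone and idempotent", {
  expect_equal(bonferroni(0.01, 7), 0.07)
  expect_equal(bonferroni(0.5, 7), 1)
  expect_equal(bonferroni(c(0.2, 0.9), 1), c(0.2, 0.9))
  expect_equal(0.05 / 7, 0.00714, tolerance = 1e-3)
  p <- sort(runif(10))
  expect_true(all(diff(bonferroni(p, 4)) >= 0))
  expect_error(bonferroni(1.2, 3), "outside")
  expect_error(bonferroni(0.5, 0), "m")
})

test_that("subgroup t test contrasts the IQ tails", {
  tab <- make_cohort_table(n = 96, eff = 0.004, seed = 12)
  res <- subgroup_ttest(tab, "association")
  expect_true(res$n_high >= 2 && res$n_low >= 2)
  # N(111,13): ~15.9% in each tail; loose binomial check
  expect_lt(abs(res$n_high / 96 - 0.159), 0.12)
  # identical tail distributions: t = 0, p = 1 (bulk of subjects at the
  # mean so mean +/- SD actually separates the tails)
  eq <- data.frame(subject_id = sprintf("S%02d", 1:40),
                   iq = c(rep(85, 5), rep(111, 30), rep(137, 5)),
                   age = 10, sex = "F",
                   hierarchy = "association", hemisphere = "L",
                   value = c(1:5, rnorm(30), 1:5))
  res2 <- subgroup_ttest(eq, "association")
  expect_equal(res2$t, 0)
  expect_equal(res2$p, 1)
  expect_equal(res2$n_high, 5)
  expect_equal(res2$n_low, 5)
})

test_that("Wilcoxon age contrast matches exact enumeration", {
  mk <- function(vals, ages) data.frame(
    subject_id = sprintf("S%02d", seq_along(vals)), age = ages,
    sex = "F", iq = 110, hierarchy = "association", hemisphere = "L",
    value = vals)
  t1 <- mk(c(1, 2, 3, 4), c(8, 9, 15, 16))
  res <- wilcoxon_age_groups(t1, age_split = 12)
  expect_equal(res$p, oracle_wilcoxon_exact_p(c(1, 2), c(3, 4)),
               tolerance = 1e-10)
  # disjoint supports, 10 vs 10: exact two-sided p = 2 / C(20, 10)
  t2 <- mk(c(1:10, 101:110), c(rep(8, 10), rep(15, 10)))
  res2 <- wilcoxon_age_groups(t2, age_split = 12)
  expect_equal(res2$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(res2$W, 0)
  expect_error(wilcoxon_age_groups(mk(1:4, rep(8, 4)), age_split = 12),
               "empty")
})
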