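#' Region-level linear model of a biomarker on IQ
#'
#' Ordinary least squares of the per-subject region mean (hemispheres and
#' bands collapsed) on IQ with age and sex as covariates of no interest.
#' Reports the raw and standardized IQ coefficient with its t test.
#'
#' @param table long-format biomarker table.
#' @param region `"association"` or `"sensorimotor"`.
#' @return Object of class `crit_lm`: tidy coefficient table (`terms`),
#'   `beta_std` (standardized IQ slope), the fitted `lm` in `$fit`, `n`.
#' @export
fit_region_linear <- function(table, region = "association") {
  d <- table[table$hierarchy == region & !is.na(table$value), , drop = FALSE]
  if (nrow(d) == 0L) stop("no records for region ", region)
  per <- stats::aggregate(d["value"],
                          by = d[c("subject_id", "age", "sex", "iq")],
                          FUN = mean)
  if (qr(cbind(1, per$iq, per$age))$rank < 3L)
    stop("rank-deficient design (iq/age collinear)")
  fit <- stats::lm(value ~ iq + age + sex, data = per)
  s <- summary(fit)$coefficients
  terms <- data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
                      statistic = s[, 3], p = s[, 4], row.names = NULL)
  structure(list(terms = terms,
                 beta_std = unname(stats::coef(fit)["iq"] *
                                     stats::sd(per$iq) / stats::sd(per$value)),
                 fit = fit, n = nrow(per), region = region),
            class = "crit_lm")
}

#' @export
print.crit_lm <- function(x, ...) {
  iq <- x$terms[x$terms$term == "iq", ]
  cat(sprintf(
    "<crit_lm> %s: IQ beta_std = %.3f (t(%d) = %.2f, p = %.3g), n = %d\n",
    x$region, x$beta_std, x$fit$df.residual, iq$statistic, iq$p, x$n))
  invisible(x)
}

prep_model_frame <- function(table, drop_missing = TRUE) {
  d <- table
  if (drop_missing) d <- d[!is.na(d$value), , drop = FALSE]
  d$subject_id <- factor(d$subject_id)
  d$sex <- factor(d$sex)
  d$hemisphere <- factor(d$hemisphere)
  d$iq_c <- d$iq - mean(d$iq)
  d$age_c <- d$age - mean(d$age)
  if (!is.null(d$band)) { d$band[is.na(d$band)] <- "none"; d$band <- factor(d$band) }
  if (!is.null(d$hierarchy))
    d$hier <- factor(d$hierarchy, levels = c("sensorimotor", "association"))
  d
}

#' Multilevel model with a hierarchy-by-IQ interaction
#'
#' Linear mixed model of the region-level biomarker on age, sex, hemisphere
#' (and band for fE/I), a hierarchy x IQ interaction, and random subject
#' intercepts; denominator degrees of freedom by the Satterthwaite
#' approximation (normal approximation is used, and labeled, if that
#' fails). With a `rank` moderator instead of the two-level hierarchy set
#' `moderator = "rank"`.
#'
#' @param table long-format biomarker table (4 or 8 records per subject at
#'   region level).
#' @param with_band include a band fixed effect (fE/I tables).
#' @param moderator `"hierarchy"` (two-level factor) or `"rank"`
#'   (continuous 1-7).
#' @return Object of class `crit_lmm`: `terms` (estimate, se, df, t, p),
#'   `ranef_var`, `fit` (lmerMod), `n_obs`, `n_subjects`, `df_method`.
#' @export
fit_multilevel <- function(table, with_band = FALSE, moderator = "hierarchy") {
  d <- prep_model_frame(table)
  d$mod_ <- if (moderator == "rank") d$rank - mean(d$rank) else d$hier
  covs <- c(if (stats::sd(d$age_c) > 0) "age_c",
            if (nlevels(d$sex) > 1L) "sex",
            if (nlevels(d$hemisphere) > 1L) "hemisphere",
            if (with_band && nlevels(d$band) > 1L) "band")
  rhs <- paste(c(covs, "mod_ * iq_c", "(1 | subject_id)"), collapse = " + ")
  fml <- stats::as.formula(paste("value ~", rhs))
  fit <- suppressMessages(lmerTest::lmer(fml, data = d))
  s <- tryCatch(stats::coef(summary(fit)), error = function(e) NULL)
  df_method <- "satterthwaite"
  if (is.null(s) || anyNA(s[, "df"])) {
    # normal-approximation fallback
    sl <- summary(lme4::lmer(fml, data = d))$coefficients
    s <- cbind(sl[, 1:3, drop = FALSE], df = Inf,
               `t value` = sl[, 3], `Pr(>|t|)` = 2 * stats::pnorm(-abs(sl[, 3])))
    df_method <- "normal-approximation"
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  terms <- data.frame(term = rownames(s), estimate = s[, "Estimate"],
                      se = s[, "Std. Error"], df = s[, "df"],
                      statistic = s[, "t value"], p = s[, "Pr(>|t|)"],
                      row.names = NULL)
  structure(list(terms = terms,
                 ranef_var = vc$vcov[vc$grp == "subject_id"],
                 fit = fit, n_obs = nrow(d),
                 n_subjects = nlevels(d$subject_id),
                 df_method = df_method, moderator = moderator),
            class = "crit_lmm")
}

#' @export
print.crit_lmm <- function(x, ...) {
  cat(sprintf("<crit_lmm> %d obs / %d subjects, df: %s, subject var %.4g\n",
              x$n_obs, x$n_subjects, x$df_method, x$ranef_var))
  print(x$terms, digits = 3)
  invisible(x)
}

interaction_term <- function(terms, focal, moderator) {
  cand <- c(paste0(focal, ":", moderator), paste0(moderator, ":", focal))
  it <- terms[terms %in% cand]
  if (length(it) == 0L)
    stop("no ", focal, " x ", moderator, " interaction in the model")
  it[1]
}

#' Johnson-Neyman interval for a moderated slope
#'
#' Probes the simple slope of a focal predictor across a grid of moderator
#' values: slope(m) = b_focal + m * b_int, with its standard error from the
#' coefficient covariance, flagging the moderator range over which the
#' slope is significant at `alpha`.
#'
#' @param model a `crit_lmm` or `crit_lm` (or bare `lm`/`lmerMod`).
#' @param focal name of the focal coefficient (e.g. `"hierassociation"`).
#' @param moderator name of the moderator coefficient (e.g. `"iq_c"`).
#' @param grid numeric grid of (centered) moderator values.
#' @param alpha significance level.
#' @return Object of class `jn_interval`: data frame `grid` with columns
#'   `moderator`, `slope`, `se`, `t`, `p`, `significant`; `boundaries`
#'   (real roots of |t| = t_crit inside the grid hull); `df`.
#' @export
johnson_neyman <- function(model, focal, moderator, grid = NULL,
                           alpha = 0.05) {
  fit <- if (inherits(model, c("crit_lmm", "crit_lm"))) model$fit else model
  b <- if (inherits(fit, "merMod")) lme4::fixef(fit) else stats::coef(fit)
  V <- as.matrix(stats::vcov(fit))
  it <- interaction_term(names(b), focal, moderator)
  if (is.null(grid)) {
    mf <- stats::model.frame(fit)
    mcol <- mf[[moderator]]
    grid <- if (is.numeric(mcol)) seq(min(mcol), max(mcol), length.out = 101)
            else seq(-2, 2, length.out = 101)
  }
  df <- if (inherits(fit, "merMod")) {
    s <- tryCatch(stats::coef(summary(fit)), error = function(e) NULL)
    if (!is.null(s) && "df" %in% colnames(s) && !is.na(s[it, "df"]))
      s[it, "df"] else Inf
  } else fit$df.residual
  tcrit <- stats::qt(1 - alpha / 2, df)

  slope <- b[focal] + grid * b[it]
  se <- sqrt(V[focal, focal] + grid^2 * V[it, it] + 2 * grid * V[focal, it])
  tval <- slope / se
  p <- 2 * stats::pt(-abs(tval), df)

  # |t| = tcrit boundaries: quadratic in m
  A <- b[it]^2 - tcrit^2 * V[it, it]
  B <- 2 * (b[focal] * b[it] - tcrit^2 * V[focal, it])
  C <- b[focal]^2 - tcrit^2 * V[focal, focal]
  disc <- B^2 - 4 * A * C
  bounds <- if (disc >= 0 && abs(A) > 1e-12) {
    r <- sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
    r[r >= min(grid) & r <= max(grid)]
  } else numeric(0)

  structure(list(grid = data.frame(moderator = grid, slope = slope, se = se,
                                   t = tval, p = p,
                                   significant = p < alpha),
                 boundaries = bounds, df = df, alpha = alpha,
                 focal = focal, moderator_name = moderator),
            class = "jn_interval")
}

#' @export
print.jn_interval <- function(x, ...) {
  sig <- x$grid$significant
  cat(sprintf("<jn_interval> %s slope over %s: significant at %d/%d grid points\n",
              x$focal, x$moderator_name, sum(sig), length(sig)))
  if (length(x$boundaries)) cat("  boundaries:",
                                paste(signif(x$boundaries, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Generalized additive mixed model with tensor-product moderation smooths
#'
#' Penalized-spline model of the biomarker with linear covariates (sex,
#' hemisphere, band where present), linear interaction terms among the
#' moderation variables, a tensor-product interaction smooth over them
#' (`ti`, so the smooth is identifiable next to the linear terms), and a
#' subject random intercept as a penalized random-effect smooth. Shrinkage
#' smoothing (`select = TRUE`, REML) lets uninformative smooths go to zero.
#'
#' At network level the moderators are (age, rank, IQ) for fE/I and
#' (rank, IQ) with a linear age main effect for the 1/f exponent (age
#' carries no exponent effect); at hierarchy level rank is replaced by the
#' two-level region factor and the smooth becomes `ti(age, iq)` (or
#' `ti(iq)`) by region.
#'
#' @param table long-format biomarker table.
#' @param biomarker `"fei"` or `"exp1f"` (controls band covariate and
#'   whether age enters the interaction).
#' @param level `"network"` (rank continuous 1-7) or `"hierarchy"`.
#' @param k basis dimensions passed to the tensor smooths.
#' @return Object of class `crit_gamm`: `parametric` and `smooth` term
#'   tables, `fit` (gam), `n_obs`, `n_subjects`, `m_effects` (count of
#'   fixed + smooth effects for Bonferroni).
#' @export
fit_gamm <- function(table, biomarker = c("fei", "exp1f"),
                     level = c("hierarchy", "network"), k = NULL) {
  biomarker <- match.arg(biomarker)
  level <- match.arg(level)
  d <- prep_model_frame(table)
  with_band <- biomarker == "fei" && !is.null(d$band) && nlevels(d$band) > 1L
  age_smooth <- biomarker == "fei"

  base <- c("sex", if (nlevels(d$hemisphere) > 1L) "hemisphere",
            if (with_band) "band")
  if (level == "network") {
    d$rank_c <- d$rank - mean(d$rank)
    lin <- if (age_smooth) "age_c * rank_c * iq_c" else "age_c + rank_c * iq_c"
    kk <- if (is.null(k)) { if (age_smooth) c(4, 4, 4) else c(4, 4) } else k
    sm <- if (age_smooth)
      sprintf("ti(age, rank, iq, k = c(%s))", paste(kk, collapse = ","))
    else sprintf("ti(rank, iq, k = c(%s))", paste(kk, collapse = ","))
  } else {
    lin <- if (age_smooth) "age_c * hier * iq_c" else "age_c + hier * iq_c"
    kk <- if (is.null(k)) { if (age_smooth) c(4, 4) else 5 } else k
    sm <- if (age_smooth)
      sprintf("ti(age, iq, by = hier, k = c(%s))", paste(kk, collapse = ","))
    else sprintf("ti(iq, by = hier, k = %s)", kk[1])
  }
  rhs <- paste(c(base, lin, sm, 's(subject_id, bs = "re")'), collapse = " + ")
  fml <- stats::as.formula(paste("value ~", rhs))
  fit <- tryCatch(mgcv::gam(fml, data = d, method = "REML", select = TRUE),
                  error = function(e) NULL)
  if (is.null(fit)) {
    # not enough unique covariate values for the requested basis: shrink it
    warning("reducing tensor basis to k = 3 per margin")
    sm2 <- gsub("k = c\\([0-9, ]+\\)", "k = c(3,3)", sm)
    sm2 <- gsub("k = [0-9]+", "k = 3", sm2)
    if (grepl("age, rank, iq", sm2)) sm2 <- sub("k = c\\(3,3\\)", "k = c(3,3,3)", sm2)
    fml <- stats::as.formula(paste("value ~",
      paste(c(base, lin, sm2, 's(subject_id, bs = "re")'), collapse = " + ")))
    fit <- mgcv::gam(fml, data = d, method = "REML", select = TRUE)
  }
  s <- summary(fit)
  pt <- data.frame(term = rownames(s$p.table), estimate = s$p.table[, 1],
                   se = s$p.table[, 2], statistic = s$p.table[, 3],
                   p = s$p.table[, 4], row.names = NULL)
  st <- data.frame(term = rownames(s$s.table), edf = s$s.table[, 1],
                   ref_df = s$s.table[, 2], statistic = s$s.table[, 3],
                   p = s$s.table[, 4], row.names = NULL)
  keep_s <- !grepl("subject_id", st$term)
  m <- (nrow(pt) - 1L) + sum(keep_s)   # fixed effects (minus intercept) + smooths
  structure(list(parametric = pt, smooth = st, fit = fit,
                 n_obs = nrow(d), n_subjects = nlevels(d$subject_id),
                 m_effects = m, biomarker = biomarker, level = level,
                 data = d),
            class = "crit_gamm")
}

#' @export
print.crit_gamm <- function(x, ...) {
  cat(sprintf("<crit_gamm> %s at %s level: %d obs / %d subjects, m = %d effects\n",
              x$biomarker, x$level, x$n_obs, x$n_subjects, x$m_effects))
  cat("parametric terms:\n"); print(x$parametric, digits = 3)
  cat("smooth terms:\n"); print(x$smooth, digits = 3)
  invisible(x)
}

#' Prediction surface at low/medium/high IQ
#'
#' Model predictions over an age x rank (or age x hierarchy) grid at IQ
#' equal to the sample mean and mean +/- 1 SD, mirroring the Low/Medium/
#' High-IQ moderation curves.
#'
#' @param gm a `crit_gamm`.
#' @param n_age grid resolution along age.
#' @return data frame (age, rank or hier, iq_level, iq, fitted, se).
#' @export
predict_iq_surface <- function(gm, n_age = 25) {
  d <- gm$data
  iqs <- mean(d$iq) + c(-1, 0, 1) * stats::sd(d$iq)
  lv <- c("low", "medium", "high")
  ages <- seq(min(d$age), max(d$age), length.out = n_age)
  mods <- if (gm$level == "network") unique(d$rank) else levels(d$hier)
  g <- expand.grid(age = ages, mod = mods, iq_i = 1:3)
  new <- data.frame(age = g$age, iq = iqs[g$iq_i],
                    sex = factor(levels(d$sex)[1], levels = levels(d$sex)),
                    hemisphere = factor(levels(d$hemisphere)[1],
                                        levels = levels(d$hemisphere)),
                    subject_id = factor(levels(d$subject_id)[1],
                                        levels = levels(d$subject_id)))
  if (!is.null(d$band) && is.factor(d$band))
    new$band <- factor(levels(d$band)[1], levels = levels(d$band))
  new$age_c <- new$age - mean(d$age)
  new$iq_c <- new$iq - mean(d$iq)
  if (gm$level == "network") {
    new$rank <- as.numeric(g$mod); new$rank_c <- new$rank - mean(d$rank)
  } else new$hier <- factor(g$mod, levels = levels(d$hier))
  pr <- mgcv::predict.gam(gm$fit, newdata = new, se.fit = TRUE,
                          exclude = "s(subject_id)",
                          newdata.guaranteed = TRUE)
  out <- data.frame(age = new$age,
                    moderator = g$mod,
                    iq_level = lv[g$iq_i], iq = new$iq,
                    fitted = as.numeric(pr$fit), se = as.numeric(pr$se.fit))
  names(out)[2] <- if (gm$level == "network") "rank" else "hierarchy"
  out
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, p * m)`; monotone in `p` and the identity at `m = 1`.
#'
#' @param pvals numeric p values in \[0, 1\].
#' @param m number of tests in the family (default `length(pvals)`).
#' @return Adjusted p values.
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
  if (m < 1) stop("m must be >= 1")
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p values outside [0, 1]")
  pmin(1, pvals * m)
}

#' High-IQ versus low-IQ subgroup contrast
#'
#' Welch two-sample t test of per-subject region means between the high-IQ
#' (>= sample mean + SD) and low-IQ (<= sample mean - SD) subgroups.
#'
#' @param table long-format biomarker table.
#' @param region hierarchy region to test.
#' @return List: `t`, `df`, `p`, group means and sizes, plus the `htest`.
#' @export
subgroup_ttest <- function(table, region = "association") {
  d <- table[table$hierarchy == region & !is.na(table$value), , drop = FALSE]
  per <- stats::aggregate(d["value"], by = d[c("subject_id", "iq")], FUN = mean)
  mu <- mean(per$iq); s <- stats::sd(per$iq)
  hi <- per$value[per$iq >= mu + s]
  lo <- per$value[per$iq <= mu - s]
  if (length(hi) < 2L || length(lo) < 2L) stop("subgroup smaller than 2")
  ht <- stats::t.test(hi, lo)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
       mean_high = mean(hi), mean_low = mean(lo),
       n_high = length(hi), n_low = length(lo), htest = ht)
}

#' Wilcoxon rank-sum comparison between age groups
#'
#' Rank-sum test (midranks for ties) of per-subject region means across two
#' age groups.
#'
#' @param table long-format biomarker table.
#' @param age_split age (years) separating the groups.
#' @param region hierarchy region.
#' @param exact force exact/approximate p (default: exact when feasible).
#' @return List: `W`, `p`, group sizes, plus the `htest`.
#' @export
wilcoxon_age_groups <- function(table, age_split = 12, region = "association",
                                exact = NULL) {
  d <- table[table$hierarchy == region & !is.na(table$value), , drop = FALSE]
  per <- stats::aggregate(d["value"], by = d[c("subject_id", "age")], FUN = mean)
  young <- per$value[per$age < age_split]
  old <- per$value[per$age >= age_split]
  if (length(young) == 0L || length(old) == 0L) stop("empty age group")
  ht <- suppressWarnings(stats::wilcox.test(young, old, exact = exact))
  list(W = unname(ht$statistic), p = ht$p.value,
       n_young = length(young), n_old = length(old), htest = ht)
}
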