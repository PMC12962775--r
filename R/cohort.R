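#' Parameters for synthetic cohorts
#'
#' Cohort-level generative settings: ages uniform over `age_range`, IQ
#' normal `(iq_mean, iq_sd)` truncated to `iq_range`, and per-record
#' biomarker values carrying a built-in rank-by-IQ interaction of size
#' `effect_interaction` (biomarker units per IQ point per rank unit) on top
#' of a subject random intercept and residual noise. Defaults mirror a
#' developmental cohort: n = 128 children aged 6-19, full-scale IQ
#' 111 +/- 13 within 71-145.
#'
#' @param n_subjects number of subjects, >= 2.
#' @param iq_mean,iq_sd IQ distribution before truncation.
#' @param iq_range length-2 truncation bounds, containing `iq_mean`.
#' @param age_range length-2 age bounds in years.
#' @param effect_interaction interaction effect size, biomarker units per
#'   (IQ point x rank unit).
#' @param subject_sd random-intercept SD, biomarker units.
#' @param resid_sd residual SD, biomarker units.
#' @param seed integer seed.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_subjects = 128, iq_mean = 111, iq_sd = 13,
                          iq_range = c(71, 145), age_range = c(6, 19),
                          effect_interaction = 0, subject_sd = 0.1,
                          resid_sd = 0.1, seed = 1L) {
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  if (length(iq_range) != 2L || iq_range[1] > iq_mean || iq_range[2] < iq_mean)
    stop("iq_range must contain iq_mean")
  if (length(age_range) != 2L || age_range[1] >= age_range[2])
    stop("age_range must be an increasing pair")
  if (iq_sd < 0 || subject_sd < 0 || resid_sd < 0) stop("SDs must be >= 0")
  structure(list(n_subjects = as.integer(n_subjects), iq_mean = iq_mean,
                 iq_sd = iq_sd, iq_range = iq_range, age_range = age_range,
                 effect_interaction = effect_interaction,
                 subject_sd = subject_sd, resid_sd = resid_sd,
                 seed = as.integer(seed)),
            class = "cohort_params")
}

rtruncnorm_reject <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2L * n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Generate a synthetic cohort with known effect structure
#'
#' Simulates subject covariates (age, sex, IQ) and long-format biomarker
#' records per subject x network x hemisphere (x band): each value is
#' `b0 + effect_interaction * (IQ - iq_mean) * (rank - 4) + u_subject + e`.
#' Centering rank at its midpoint (4) makes the injected term a pure
#' rank-by-IQ interaction.
#'
#' @param c a [cohort_params()].
#' @param networks data frame with columns `network` and `rank` (1-7), e.g.
#'   unique rows of [default_network_map()]; or a bare integer rank vector.
#' @param bands optional character vector of band labels; `NULL` emits one
#'   record per network x hemisphere.
#' @param biomarker label stored in the `biomarker` column
#'   (`"fei"` or `"exp1f"`).
#' @param b0 grand intercept, biomarker units.
#' @return A list with `covariates` (one row per subject) and `table`
#'   (long-format records: subject_id, age, sex, iq, network, rank,
#'   hierarchy, hemisphere, band, biomarker, value, missing).
#' @examples
#' co <- generate_cohort(cohort_params(n_subjects = 8, seed = 1))
#' head(co$table)
#' @export
generate_cohort <- function(c, networks = yeo7_ranks(), bands = NULL,
                            biomarker = "exp1f", b0 = 1.46) {
  stopifnot(inherits(c, "cohort_params"))
  if (is.numeric(networks)) {
    networks <- data.frame(network = paste0("net", networks),
                           rank = as.integer(networks))
  }
  if (nrow(networks) == 0L) stop("empty network rank list")
  if (!all(networks$rank %in% 1:7)) stop("network ranks must lie in 1..7")

  set.seed(c$seed)
  covariates <- data.frame(
    subject_id = sprintf("S%03d", seq_len(c$n_subjects)),
    age = stats::runif(c$n_subjects, c$age_range[1], c$age_range[2]),
    sex = sample(c("F", "M"), c$n_subjects, replace = TRUE),
    iq = rtruncnorm_reject(c$n_subjects, c$iq_mean, c$iq_sd,
                           c$iq_range[1], c$iq_range[2]),
    stringsAsFactors = FALSE)
  u <- stats::rnorm(c$n_subjects, 0, c$subject_sd)

  hemis <- c("L", "R")
  band_lv <- if (is.null(bands)) "none" else bands
  grid <- expand.grid(subject = seq_len(c$n_subjects),
                      net = seq_len(nrow(networks)),
                      hemisphere = hemis, band = band_lv,
                      stringsAsFactors = FALSE)
  rank <- networks$rank[grid$net]
  iq <- covariates$iq[grid$subject]
  value <- b0 +
    c$effect_interaction * (iq - c$iq_mean) * (rank - 4) +
    u[grid$subject] +
    stats::rnorm(nrow(grid), 0, c$resid_sd)

  tab <- data.frame(
    subject_id = covariates$subject_id[grid$subject],
    age = covariates$age[grid$subject],
    sex = covariates$sex[grid$subject],
    iq = iq,
    network = networks$network[grid$net],
    rank = rank,
    hierarchy = ifelse(rank <= 3, "sensorimotor", "association"),
    hemisphere = grid$hemisphere,
    band = grid$band,
    biomarker = biomarker,
    value = value,
    missing = FALSE,
    stringsAsFactors = FALSE)
  list(covariates = covariates, table = tab)
}

#' Canonical Yeo7 network ranks
#'
#' The seven resting-state networks ordered along the
#' sensorimotor-association cortical hierarchy; rank 1-7 is the continuous
#' hierarchy predictor, with sensorimotor = ranks 1-3 and association =
#' ranks 4-7. The ordering is a declared convention of this package.
#'
#' @return data frame with columns `network`, `rank`, `hierarchy`.
#' @export
yeo7_ranks <- function() {
  data.frame(
    network = c("visual", "somatomotor", "dorsal_attention",
                "salience", "limbic", "control", "default"),
    rank = 1:7,
    hierarchy = c(rep("sensorimotor", 3), rep("association", 4)),
    stringsAsFactors = FALSE)
}

#' Write a cohort to CSV files
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$table, file.path(dir, "biomarkers.csv"),
                   row.names = FALSE)
  invisible(dir)
}
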