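#' Per-channel biomarkers for one recording
#'
#' Runs the full biomarker battery on every channel of a recording: fE/I
#' and DFA in the two fixed alpha bands (or the individualized half-bands),
#' the 1-5 Hz aperiodic exponent and the broadband alpha-peak parameters.
#'
#' @param ts multichannel [time_series()].
#' @param band_mode `"fixed"` (8.3-10.5 / 10.5-13.4 Hz) or `"iaf"`
#'   (PAF +/- 2 Hz split into half-bands).
#' @param window_s,overlap,dfa_gate fE/I parameters (see [compute_fei()]).
#' @param dfa_fit_range_s DFA fit range in seconds.
#' @return data frame, one row per channel x band: `label`, `band`,
#'   `band_lo`, `band_hi`, `fei`, `r`, `dfa`, `n_windows`, `valid`,
#'   `reason`, `exp1f`, `offset`, `paf`, `peak_height`.
#' @export
compute_biomarkers <- function(ts, band_mode = c("fixed", "iaf"),
                               window_s = 5, overlap = 0.8, dfa_gate = 0.6,
                               dfa_fit_range_s = c(2, 20)) {
  band_mode <- match.arg(band_mode)
  rows <- lapply(seq_along(ts$labels), function(i) {
    ch <- ts[i]
    w <- welch_psd(ch)
    spec_lo <- fit_aperiodic_lowfreq(w$freqs, w$psd)
    spec_bb <- fit_periodic_broadband(w$freqs, w$psd)
    if (band_mode == "fixed") {
      bands <- alpha_bands()
    } else {
      if (is.na(spec_bb$paf)) {
        return(data.frame(label = ts$labels[i],
                          band = c("iaf_lo", "iaf_hi"),
                          band_lo = NA_real_, band_hi = NA_real_,
                          fei = NA_real_, r = NA_real_, dfa = NA_real_,
                          n_windows = 0L, valid = FALSE,
                          reason = "no alpha peak",
                          exp1f = spec_lo$beta, offset = spec_lo$offset,
                          paf = NA_real_, peak_height = NA_real_,
                          stringsAsFactors = FALSE))
      }
      bands <- list(iaf_lo = band(spec_bb$paf - 2, spec_bb$paf),
                    iaf_hi = band(spec_bb$paf, spec_bb$paf + 2))
    }
    do.call(rbind, lapply(names(bands), function(bn) {
      fr <- compute_fei(ch, bands[[bn]], window_s = window_s,
                        overlap = overlap, dfa_gate = dfa_gate,
                        dfa_fit_range_s = dfa_fit_range_s)
      data.frame(label = ts$labels[i], band = bn,
                 band_lo = bands[[bn]]$f_lo, band_hi = bands[[bn]]$f_hi,
                 fei = fr$fei, r = fr$r, dfa = fr$dfa_exponent,
                 n_windows = fr$n_windows, valid = fr$valid,
                 reason = fr$reason,
                 exp1f = spec_lo$beta, offset = spec_lo$offset,
                 paf = spec_bb$paf, peak_height = spec_bb$peak_height,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pipeline configuration
#'
#' Validated settings for [run_pipeline()]. With `input_dir = NULL` the
#' pipeline simulates its own cohort (`n_subjects` recordings of
#' `duration_s` seconds on the channels of `map`).
#'
#' @param input_dir directory of per-subject EDF files named
#'   `<subject_id>.edf` plus `covariates.csv`, or `NULL` to simulate.
#' @param n_subjects,duration_s,fs simulated cohort dimensions.
#' @param band_mode,window_s,overlap,dfa_gate,dfa_fit_range_s biomarker
#'   settings (see [compute_biomarkers()]).
#' @param map a [network_map()].
#' @param impute impute missing fE/I cells (see [impute_missing_fei()]).
#' @param effect_interaction,hurst,coupling,beta_aperiodic simulation truth.
#' @param seed master seed; per-subject substreams are derived from it, so
#'   results do not depend on processing order.
#' @param out_dir output directory for CSVs and the run log.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir = NULL, n_subjects = 32,
                            duration_s = 180, fs = 250,
                            band_mode = "fixed", window_s = 5, overlap = 0.8,
                            dfa_gate = 0.6, dfa_fit_range_s = c(2, 20),
                            map = default_network_map(), impute = TRUE,
                            effect_interaction = 0, hurst = 0.75,
                            coupling = 0, beta_aperiodic = 1.46,
                            seed = 1L, out_dir = tempfile("critEEG_run_")) {
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop("input_dir does not exist: ", input_dir)
  if (window_s < 3 || window_s > 6)
    warning("window_s outside the supported 3-6 s range")
  if (overlap < 0.5 || overlap >= 1) stop("overlap out of range")
  stopifnot(inherits(map, "network_map"))
  structure(list(input_dir = input_dir, n_subjects = n_subjects,
                 duration_s = duration_s, fs = fs, band_mode = band_mode,
                 window_s = window_s, overlap = overlap, dfa_gate = dfa_gate,
                 dfa_fit_range_s = dfa_fit_range_s, map = map,
                 impute = impute, effect_interaction = effect_interaction,
                 hurst = hurst, coupling = coupling,
                 beta_aperiodic = beta_aperiodic,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Loads a structured text config (any subset of the [pipeline_config()]
#' arguments; `map` may be a path to a network-map CSV) and validates it.
#'
#' @param path YAML file path.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$map) && is.character(y$map))
    y$map <- network_map(utils::read.csv(y$map, stringsAsFactors = FALSE))
  if (!is.null(y$dfa_fit_range_s)) y$dfa_fit_range_s <- unlist(y$dfa_fit_range_s)
  do.call(pipeline_config, y)
}

subject_seed <- function(master, k) {
  as.integer((as.numeric(master) * 7919 + k * 104729) %% 2147483647)
}

simulate_subject_recording <- function(cfg, covs, k) {
  labels <- cfg$map$label
  # per-channel coupling tied to the subject's IQ-by-rank effect so the
  # injected interaction survives the biomarker stage; per-subject peak
  # alpha frequency varies across the cohort as in real children
  n <- length(labels)
  mat <- matrix(0, n, cfg$duration_s * cfg$fs)
  set.seed(subject_seed(cfg$seed, k))
  paf_k <- stats::runif(1, 9.5, 11.5)
  for (j in seq_len(n)) {
    kap <- cfg$coupling +
      cfg$effect_interaction * (covs$iq[k] - 111) * (cfg$map$rank[j] - 4)
    kap <- max(-1, min(1, kap))
    sp <- signal_params(duration_s = cfg$duration_s, fs = cfg$fs,
                        f_alpha = paf_k,
                        hurst = cfg$hurst, coupling = kap,
                        beta_aperiodic = cfg$beta_aperiodic,
                        seed = subject_seed(cfg$seed, k * 1000L + j))
    mat[j, ] <- channel(generate_signal(sp))
  }
  time_series(mat, cfg$fs, labels)
}

#' Run the end-to-end pipeline
#'
#' Reads (or simulates) one recording per subject, computes per-channel
#' biomarkers, aggregates them over the ranked networks, collapses to the
#' sensorimotor-association hierarchy, optionally imputes missing fE/I,
#' fits the headline models (region-level OLS, multilevel hierarchy x IQ,
#' GAMMs) and writes all tables plus a run log to `out_dir`. Per-subject
#' failures are isolated: the subject is logged and dropped, the pipeline
#' continues.
#'
#' @param cfg a [pipeline_config()].
#' @return Invisibly, a list: `channel_values`, `fei_table`, `exp1f_table`,
#'   `fei_region`, `exp1f_region`, `models`, `failures`, `log`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cfg$out_dir, "run_log.txt")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                               append = TRUE)
  cat("", file = logf)
  logline("critEEG pipeline | R %s | critEEG %s", getRversion(),
          as.character(utils::packageVersion("critEEG")))
  logline("config: band=%s window=%gs overlap=%g gate=%g impute=%s seed=%d",
          cfg$band_mode, cfg$window_s, cfg$overlap, cfg$dfa_gate,
          cfg$impute, cfg$seed)

  if (is.null(cfg$input_dir)) {
    cp <- cohort_params(n_subjects = cfg$n_subjects, seed = cfg$seed)
    covs <- generate_cohort(cp)$covariates
    get_recording <- function(k) simulate_subject_recording(cfg, covs, k)
  } else {
    covs <- utils::read.csv(file.path(cfg$input_dir, "covariates.csv"),
                            stringsAsFactors = FALSE)
    get_recording <- function(k)
      read_edf(file.path(cfg$input_dir, paste0(covs$subject_id[k], ".edf")))
  }

  per_channel <- list(); failures <- character(0)
  for (k in seq_len(nrow(covs))) {
    res <- tryCatch({
      ts <- get_recording(k)
      bm <- compute_biomarkers(ts, band_mode = cfg$band_mode,
                               window_s = cfg$window_s, overlap = cfg$overlap,
                               dfa_gate = cfg$dfa_gate,
                               dfa_fit_range_s = cfg$dfa_fit_range_s)
      cbind(covs[k, c("subject_id", "age", "sex", "iq")], bm,
            row.names = NULL)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, covs$subject_id[k])
      logline("subject %s FAILED: %s", covs$subject_id[k],
              conditionMessage(res))
    } else {
      per_channel[[length(per_channel) + 1L]] <- res
      logline("subject %s: %d channel-band rows, %d valid fE/I",
              covs$subject_id[k], nrow(res), sum(res$valid))
    }
  }
  if (length(per_channel) == 0L) stop("all subjects failed")
  chan <- do.call(rbind, per_channel)

  fei_vals <- data.frame(chan[c("subject_id", "age", "sex", "iq", "label",
                                "band")], value = chan$fei)
  exp_vals <- unique(data.frame(chan[c("subject_id", "age", "sex", "iq",
                                       "label")], value = chan$exp1f))
  fei_tab <- aggregate_to_networks(fei_vals, cfg$map, biomarker = "fei")
  exp_tab <- aggregate_to_networks(exp_vals, cfg$map, biomarker = "exp1f")
  logline("tables: fei %d records (%d missing), exp1f %d records",
          nrow(fei_tab), sum(fei_tab$missing), nrow(exp_tab))
  if (cfg$impute && any(fei_tab$missing)) {
    fei_tab <- tryCatch(impute_missing_fei(fei_tab, seed = cfg$seed),
                        error = function(e) {
                          logline("imputation skipped: %s", conditionMessage(e))
                          fei_tab
                        })
  }

  fei_reg <- collapse_hierarchy(fei_tab)
  exp_reg <- collapse_hierarchy(exp_tab)

  models <- list(
    lm_fei_assoc = try_model(fit_region_linear(fei_reg, "association")),
    lm_fei_sens = try_model(fit_region_linear(fei_reg, "sensorimotor")),
    lm_exp_assoc = try_model(fit_region_linear(exp_reg, "association")),
    lm_exp_sens = try_model(fit_region_linear(exp_reg, "sensorimotor")),
    lmm_fei = try_model(fit_multilevel(fei_reg, with_band = TRUE)),
    lmm_exp = try_model(fit_multilevel(exp_reg)),
    gamm_fei = try_model(fit_gamm(fei_reg, "fei", "hierarchy")),
    gamm_exp = try_model(fit_gamm(exp_reg, "exp1f", "hierarchy")))

  utils::write.csv(chan, file.path(cfg$out_dir, "channel_biomarkers.csv"),
                   row.names = FALSE)
  utils::write.csv(fei_tab, file.path(cfg$out_dir, "fei_network.csv"),
                   row.names = FALSE)
  utils::write.csv(exp_tab, file.path(cfg$out_dir, "exp1f_network.csv"),
                   row.names = FALSE)
  utils::write.csv(fei_reg, file.path(cfg$out_dir, "fei_region.csv"),
                   row.names = FALSE)
  utils::write.csv(exp_reg, file.path(cfg$out_dir, "exp1f_region.csv"),
                   row.names = FALSE)
  for (nm in names(models)) {
    m <- models[[nm]]
    if (is.null(m)) next
    tab <- if (inherits(m, "crit_gamm")) m$parametric else m$terms
    utils::write.csv(tab, file.path(cfg$out_dir, paste0("model_", nm, ".csv")),
                     row.names = FALSE)
  }
  logline("failures: %d (%s)", length(failures),
          paste(failures, collapse = ", "))
  logline("done")
  invisible(list(channel_values = chan, fei_table = fei_tab,
                 exp1f_table = exp_tab, fei_region = fei_reg,
                 exp1f_region = exp_reg, models = models,
                 failures = failures, log = logf))
}

try_model <- function(expr) tryCatch(expr, error = function(e) NULL)

#' Sensitivity sweep over fE/I window parameters
#'
#' Re-runs the biomarker + headline-model stage for each (window length,
#' overlap) cell of a grid inside the supported 3-6 s / 75-85% ranges and
#' reports the sign and significance of the hierarchy x IQ interaction per
#' cell.
#'
#' @param cfg a [pipeline_config()].
#' @param window_grid window lengths in seconds (3-6).
#' @param overlap_grid overlaps (0.75-0.85).
#' @return data frame: one row per grid cell with the interaction estimate,
#'   p value, Bonferroni-adjusted p and sign.
#' @export
run_sensitivity_sweep <- function(cfg, window_grid = c(4, 5),
                                  overlap_grid = c(0.75, 0.85)) {
  if (length(window_grid) == 0L || length(overlap_grid) == 0L)
    stop("empty sweep grid")
  if (any(window_grid < 3 | window_grid > 6))
    stop("window_grid outside 3-6 s")
  if (any(overlap_grid < 0.75 | overlap_grid > 0.85))
    stop("overlap_grid outside 0.75-0.85")
  cells <- expand.grid(window_s = window_grid, overlap = overlap_grid)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    ci <- cfg
    ci$window_s <- cells$window_s[i]
    ci$overlap <- cells$overlap[i]
    ci$impute <- FALSE                       # control analyses: no imputation
    ci$out_dir <- file.path(cfg$out_dir,
                            sprintf("sweep_w%g_o%g", ci$window_s, ci$overlap))
    res <- run_pipeline(ci)
    lmm <- res$models$lmm_fei
    it <- lmm$terms[grepl(":", lmm$terms$term), ][1, ]
    m <- nrow(lmm$terms) - 1L
    data.frame(window_s = ci$window_s, overlap = ci$overlap,
               estimate = it$estimate, p = it$p,
               p_bonf = bonferroni(it$p, m), sign = sign(it$estimate))
  })
  do.call(rbind, out)
}
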