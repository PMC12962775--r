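#' Channel-to-network map
#'
#' Validates a mapping from channel/parcel labels to ranked functional
#' networks: columns `label`, `network`, `rank` (1-7), `hierarchy`
#' (`sensorimotor`/`association`), `hemisphere` (`L`/`R`).
#'
#' @param df data frame with the columns above.
#' @return The validated data frame, classed `network_map`.
#' @export
network_map <- function(df) {
  need <- c("label", "network", "rank", "hierarchy", "hemisphere")
  if (!all(need %in% names(df))) stop("network map needs columns: ",
                                      paste(need, collapse = ", "))
  if (!all(df$rank %in% 1:7)) stop("ranks must lie in 1..7")
  if (!all(df$hierarchy %in% c("sensorimotor", "association")))
    stop("hierarchy must be 'sensorimotor' or 'association'")
  if (!all(df$hemisphere %in% c("L", "R"))) stop("hemisphere must be L or R")
  bad <- tapply(df$hierarchy, df$network, function(h) length(unique(h)) > 1L)
  if (any(bad)) stop("inconsistent hierarchy within network: ",
                     paste(names(bad)[bad], collapse = ", "))
  if (anyDuplicated(df$label)) stop("duplicated channel labels in map")
  class(df) <- c("network_map", "data.frame")
  df
}

#' Default sensor-space network map for a 10-20 montage
#'
#' A declared, editable convention assigning the 16 lateral electrodes of
#' the 10-20 system to the seven ranked networks per hemisphere (midline
#' electrodes Fz, Cz, Pz are deliberately unmapped — exclude them or supply
#' your own map). The assignment is a sensor-space analog of the cortical
#' parcellation, not a source model.
#'
#' @return A [network_map()].
#' @export
default_network_map <- function() {
  y <- yeo7_ranks()
  lab <- list(
    visual = c("O1", "O2"), somatomotor = c("C3", "C4"),
    dorsal_attention = c("P7", "P8"), salience = c("F7", "F8"),
    limbic = c("T7", "T8"), control = c("F3", "F4"),
    default = c("P3", "P4"))
  rows <- do.call(rbind, lapply(names(lab), function(nw) {
    data.frame(label = lab[[nw]], network = nw,
               rank = y$rank[y$network == nw],
               hierarchy = y$hierarchy[y$network == nw],
               hemisphere = c("L", "R"), stringsAsFactors = FALSE)
  }))
  network_map(rows)
}

#' Aggregate per-channel biomarker values into network records
#'
#' Averages valid channel values into one record per network x hemisphere
#' (x band); a cell whose channels are all missing stays missing. Unknown
#' labels are an error unless explicitly excluded.
#'
#' @param values data frame with columns `subject_id`, `label`, `value` and
#'   optionally `band` plus subject covariates (`age`, `sex`, `iq`) carried
#'   through.
#' @param map a [network_map()].
#' @param biomarker stored in the output `biomarker` column.
#' @param exclude character vector of labels to drop silently (e.g. midline).
#' @return Long-format `BiomarkerTable` data frame (one row per subject x
#'   network x hemisphere x band) with `missing` flags.
#' @export
aggregate_to_networks <- function(values, map, biomarker = "fei",
                                  exclude = character(0)) {
  stopifnot(inherits(map, "network_map"))
  values <- values[!(values$label %in% exclude), , drop = FALSE]
  unknown <- setdiff(unique(values$label), map$label)
  if (length(unknown) > 0L)
    stop("unmapped channel labels (map them or exclude): ",
         paste(unknown, collapse = ", "))
  idx <- match(values$label, map$label)
  values$network <- map$network[idx]
  values$rank <- map$rank[idx]
  values$hierarchy <- map$hierarchy[idx]
  values$hemisphere <- map$hemisphere[idx]
  if (is.null(values$band)) values$band <- "none"
  values$band[is.na(values$band)] <- "none"

  keys <- c("subject_id", "network", "rank", "hierarchy", "hemisphere", "band")
  agg <- stats::aggregate(values["value"], by = values[keys],
                          FUN = function(v) mean(v, na.rm = TRUE), drop = FALSE)
  agg <- agg[!is.na(agg$subject_id) & !is.na(agg$network), , drop = FALSE]
  # aggregate() with drop=FALSE crosses network with rank/hierarchy; keep
  # only combinations that exist in the map
  agg <- agg[paste(agg$network, agg$rank, agg$hierarchy, agg$hemisphere) %in%
               paste(map$network, map$rank, map$hierarchy, map$hemisphere),
             , drop = FALSE]
  agg$value[is.nan(agg$value)] <- NA_real_

  covs <- unique(values[intersect(c("subject_id", "age", "sex", "iq"),
                                  names(values))])
  out <- merge(agg, covs, by = "subject_id", all.x = TRUE, sort = FALSE)
  out$biomarker <- biomarker
  out$missing <- is.na(out$value)
  cols <- c("subject_id", intersect(c("age", "sex", "iq"), names(out)),
            "network", "rank", "hierarchy", "hemisphere", "band",
            "biomarker", "value", "missing")
  out <- out[do.call(order, out[c("subject_id", "rank", "hemisphere", "band")]),
             cols]
  rownames(out) <- NULL
  out
}

#' Collapse network records to the sensorimotor-association hierarchy
#'
#' Per-subject mean over the networks within each hierarchy x hemisphere
#' (x band) cell; missing members are ignored, an all-missing cell stays
#' missing.
#'
#' @param table a long-format biomarker table with `rank` and `hierarchy`.
#' @return The collapsed table (two regions instead of seven networks),
#'   with `rank` replaced by the mean rank of the contributing networks.
#' @export
collapse_hierarchy <- function(table) {
  stopifnot(all(c("hierarchy", "value") %in% names(table)))
  if (is.null(table$band)) table$band <- "none"
  table$band[is.na(table$band)] <- "none"
  keys <- c("subject_id", "hierarchy", "hemisphere", "band")
  agg <- stats::aggregate(table[c("value", "rank")], by = table[keys],
                          FUN = function(v) mean(v, na.rm = TRUE))
  agg$value[is.nan(agg$value)] <- NA_real_
  covs <- unique(table[intersect(c("subject_id", "age", "sex", "iq", "biomarker"),
                                 names(table))])
  out <- merge(agg, covs, by = "subject_id", all.x = TRUE, sort = FALSE)
  out$network <- out$hierarchy
  out$missing <- is.na(out$value)
  out <- out[do.call(order, out[c("subject_id", "hierarchy", "hemisphere", "band")]), ]
  rownames(out) <- NULL
  out
}

#' Impute missing fE/I values by chained random forests
#'
#' Iterated chained prediction of missing values from subject covariates and
#' record keys (age, sex, IQ, rank, hemisphere, band) with regression
#' forests, initialized from cell means and iterated until the out-of-bag
#' error stops improving (or `max_iter`). Imputed cells keep their
#' `missing = TRUE` flag so control analyses can drop them.
#'
#' @param table long-format biomarker table with `missing` flags.
#' @param n_trees forest size per iteration.
#' @param max_iter maximum chained iterations.
#' @param seed integer seed (imputation is deterministic given it).
#' @return The table with missing `value`s filled; attribute `"oob_rmse"`
#'   carries the per-iteration out-of-bag error trace.
#' @export
impute_missing_fei <- function(table, n_trees = 100, max_iter = 5, seed = 1L) {
  miss <- is.na(table$value)
  if (!any(miss)) return(table)
  if (mean(miss) >= 0.5) stop("more than 50% missing; refusing to impute")
  preds <- intersect(c("age", "sex", "iq", "rank", "hemisphere", "band"),
                     names(table))
  x <- table[preds]
  x[] <- lapply(x, function(col) if (is.character(col)) factor(col) else col)
  x <- x[vapply(x, function(c) length(unique(c)) > 1L, TRUE)]
  if (ncol(x) == 0L) {
    # degenerate predictors: fall back to within-cell mean imputation
    cell <- interaction(table$network, table$hemisphere, table$band, drop = TRUE)
    mu <- tapply(table$value, cell, mean, na.rm = TRUE)
    table$value[miss] <- mu[cell[miss]]
    attr(table, "fallback") <- "cell-mean"
    return(table)
  }
  # start from within-cell means
  cell <- interaction(table$network, table$hemisphere, table$band, drop = TRUE)
  mu <- tapply(table$value, cell, mean, na.rm = TRUE)
  filled <- table$value
  filled[miss] <- mu[cell[miss]]
  filled[is.na(filled)] <- mean(table$value, na.rm = TRUE)

  set.seed(as.integer(seed))
  sid <- factor(table$subject_id)
  oob <- rep(NA_real_, max_iter)
  best <- Inf
  for (it in seq_len(max_iter)) {
    # sibling information: leave-one-out subject mean from current fill
    tot <- tapply(filled, sid, sum); cnt <- tapply(filled, sid, length)
    x$sibling_mean <- (tot[sid] - filled) / (cnt[sid] - 1)
    fit <- ranger::ranger(y = filled[!miss], x = x[!miss, , drop = FALSE],
                          num.trees = n_trees,
                          seed = as.integer(seed) + it)
    oob[it] <- sqrt(fit$prediction.error)
    filled[miss] <- stats::predict(fit, x[miss, , drop = FALSE])$predictions
    if (oob[it] >= best - 1e-8) break
    best <- oob[it]
  }
  table$value <- filled
  attr(table, "oob_rmse") <- oob[!is.na(oob)]
  table
}
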