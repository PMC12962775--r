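chan_values <- function(n_sub = 4, map = default_network_map(), bands = NULL,
                        seed = 1) {
  set.seed(seed)
  grid <- expand.grid(subject_id = sprintf("S%02d", seq_len(n_sub)),
                      label = map$label,
                      band = if (is.null(bands)) "none" else bands,
                      stringsAsFactors = FALSE)
  covs <- data.frame(subject_id = sprintf("S%02d", seq_len(n_sub)),
                     age = runif(n_sub, 6, 19), sex = "F",
                     iq = rnorm(n_sub, 111, 13))
  out <- merge(grid, covs, by = "subject_id")
  out$value <- rnorm(nrow(out), 1.5, 0.1)
  out
}

test_that("network aggregation yields the canonical record counts", {
  map <- default_network_map()
  v <- chan_values(128)
  tab <- aggregate_to_networks(v, map, biomarker = "exp1f")
  expect_equal(nrow(tab), 1792L)                       # 7 x 2 x 128
  expect_equal(nrow(collapse_hierarchy(tab)), 512L)    # 2 x 2 x 128

  vf <- chan_values(16, bands = c("alpha_lo", "alpha_hi"))
  tf <- aggregate_to_networks(vf, map)
  expect_equal(nrow(tf), 7 * 2 * 2 * 16)
  expect_equal(nrow(collapse_hierarchy(tf)), 2 * 2 * 2 * 16)
})

test_that("aggregation is the identity for single-channel networks and is
           permutation invariant", {
  map <- default_network_map()
  v <- chan_values(3, seed = 7)
  t1 <- aggregate_to_networks(v, map)
  t2 <- aggregate_to_networks(v[sample(nrow(v)), ], map)
  expect_equal(t1, t2)
  # one channel per network x hemisphere in the default map -> identity
  i <- sample(nrow(v), 1)
  rec <- t1[t1$subject_id == v$subject_id[i] &
              t1$network == map$network[map$label == v$label[i]] &
              t1$hemisphere == map$hemisphere[map$label == v$label[i]], ]
  expect_equal(rec$value, v$value[i])
})

test_that("missingness stays local to the gated cell", {
  map <- default_network_map()
  v <- chan_values(3)
  v$value[v$label == "O1" & v$subject_id == "S01"] <- NA
  tab <- aggregate_to_networks(v, map)
  gone <- tab$subject_id == "S01" & tab$network == "visual" &
    tab$hemisphere == "L"
  expect_true(all(tab$missing[gone]))
  expect_false(any(tab$missing[!gone]))
})

test_that("unknown labels are rejected unless excluded", {
  map <- default_network_map()
  v <- chan_values(2)
  v$label[1] <- "Cz"
  expect_error(aggregate_to_networks(v, map), "Cz")
  expect_silent(tab <- aggregate_to_networks(v, map, exclude = "Cz"))
})

test_that("map validation enforces structure", {
  m <- default_network_map()
  expect_s3_class(m, "network_map")
  bad <- m; bad$rank[1] <- 9
  expect_error(network_map(bad), "rank")
  bad2 <- m; bad2$hierarchy[1] <- "association"
  expect_error(network_map(bad2), "inconsistent")
  # csv round trip
  f <- tempfile(fileext = ".csv")
  write.csv(m, f, row.names = FALSE)
  expect_equal(network_map(read.csv(f))$label, m$label)
})

test_that("imputation recovers masked values better than mean fill", {
  co <- generate_cohort(cohort_params(n_subjects = 48,
                                      effect_interaction = 0.002, seed = 3))
  tab <- co$table
  set.seed(11)
  idx <- sample(nrow(tab), round(0.1 * nrow(tab)))
  tab$value[idx] <- NA
  tab$missing <- is.na(tab$value)

  imp <- impute_missing_fei(tab, seed = 5)
  rf_rmse <- sqrt(mean((imp$value[idx] - co$table$value[idx])^2))
  mean_rmse <- sqrt(mean((mean(tab$value, na.rm = TRUE) -
                            co$table$value[idx])^2))
  expect_lt(rf_rmse, mean_rmse)

  imp2 <- impute_missing_fei(tab, seed = 5)
  expect_identical(imp$value, imp2$value)      # seeded determinism
  expect_true(all(imp$missing[idx]))           # flags preserved

  full <- impute_missing_fei(co$table)
  expect_identical(full$value, co$table$value) # identity on complete data

  worst <- tab; worst$value[] <- NA
  expect_error(impute_missing_fei(worst), "50%")
})
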