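test_that("metric suite matches hand cases and a brute-force recomputation", {
  # perfect predictions
  m <- compute_metrics(c(8, 10, 12), c(8, 10, 12))
  expect_equal(m$mse, 0); expect_equal(m$mae, 0); expect_equal(m$r2, 1)
  expect_equal(m$mpe, 0); expect_equal(m$p10, 100)

  # symmetric +/-10%: zero bias, 10% spread, all within 10%
  m2 <- compute_metrics(c(10, 10), c(11, 9))
  expect_equal(m2$mpe, 0)
  expect_equal(m2$rmsrpe, 10)
  expect_equal(m2$p10, 100)

  # constant prediction at the observed mean has R2 = 0
  y <- c(6, 9, 13)
  m3 <- compute_metrics(y, rep(mean(y), 3))
  expect_equal(m3$r2, 0)

  # sign convention: overprediction gives positive MPE
  expect_gt(compute_metrics(10, 12)$mpe, 0)

  # brute-force oracle agreement on 1,000 random pairs
  set.seed(101)
  obs <- runif(1000, 2, 25)
  pred <- obs * (1 + rnorm(1000, 0, 0.25))
  m4 <- compute_metrics(obs, pred)
  o <- oracle_metrics(obs, pred)
  for (k in names(o)) {
    expect_lt(abs(m4[[k]] - o[[k]]) / max(1e-12, abs(o[[k]])), 1e-10)
  }

  expect_error(compute_metrics(c(10, -1), c(9, 9)), "positive")
  expect_true(is.na(compute_metrics(10, 9)$r2))
  expect_true(m4$p10 <= m4$p20 && m4$p20 <= m4$p30)
})

test_that("fold assignment partitions patients and balances trough bins", {
  sim <- simulate_cohort(cohort_config(n_patients = 40, seed = 55))
  f <- make_folds(sim$cohort, 5, seed = 9)
  expect_length(f, 40)
  expect_setequal(unique(f), 1:5)
  expect_identical(f, make_folds(sim$cohort, 5, seed = 9))
  expect_false(identical(f, make_folds(sim$cohort, 5, seed = 10)))
  # within each trough-count bin the fold sizes are balanced within 1
  nt <- vapply(sim$cohort, function(r) nrow(r$troughs), integer(1))
  bin <- pmin(nt, 4)
  for (b in unique(bin)) {
    sizes <- table(factor(f[bin == b], levels = 1:5))
    expect_lte(diff(range(sizes)), 1)
  }
  expect_error(make_folds(sim$cohort, 41, seed = 1), "exceeds")
})

test_that("cross-validation keeps patients out of their own training folds", {
  sim <- simulate_cohort(cohort_config(n_patients = 30, seed = 66))
  cv <- crossvalidate(sim$cohort, "xgb_mech", k = 3, seed = 66,
                      xgb_cfg = xgb_config(
                        grid = data.frame(max_depth = 2L, eta = 0.3,
                                          nrounds = 30L, subsample = 1),
                        seed = 66))
  folds <- make_folds(sim$cohort, 3, seed = 66)
  expect_equal(unname(folds[cv$predictions$patient_id]),
               cv$predictions$fold)
  # pooled metrics recomputed independently from the predictions table
  o <- oracle_metrics(cv$predictions$observed, cv$predictions$predicted)
  expect_equal(cv$pooled$mse, o$mse, tolerance = 1e-12)
  expect_equal(cv$pooled$r2, o$r2, tolerance = 1e-12)
  expect_equal(nrow(cv$per_fold), 3)
})

test_that("attainment stratification sums to 100% and matches brute force", {
  set.seed(12)
  decisions <- data.frame(
    observed = runif(200, 4, 16),
    category = sample(c("within", "below", "above"), 200, replace = TRUE),
    target_index = sample(2:5, 200, replace = TRUE)
  )
  ta <- target_attainment(decisions, target = c(8, 12))
  bs <- ta$by_stratum
  ok <- bs$n > 0
  expect_equal(bs$pct_below[ok] + bs$pct_within[ok] + bs$pct_above[ok],
               rep(100, sum(ok)))
  # brute force for the "within" stratum
  d <- decisions[decisions$category == "within", ]
  expect_equal(bs$pct_within[bs$stratum == "within"],
               100 * sum(d$observed >= 8 & d$observed <= 12) / nrow(d))
  # boundary trough at exactly 8 counts as within (closed interval)
  ta8 <- target_attainment(data.frame(observed = 8, category = "within",
                                      target_index = 2))
  expect_equal(ta8$by_stratum$pct_within[1], 100)
  # all troughs at 10 -> 100% within in every non-empty stratum
  ta10 <- target_attainment(data.frame(observed = rep(10, 6),
                                       category = rep(c("within", "below"),
                                                      3),
                                       target_index = 2))
  expect_true(all(ta10$by_stratum$pct_within[ta10$by_stratum$n > 0] == 100))
  # empty stratum reported with n = 0, no division
  expect_true(any(ta10$by_stratum$n == 0))
  ht <- attainment_test(decisions)
  expect_s3_class(ht, "htest")
})

test_that("permutation importance is zero for constant or unused features", {
  sim <- simulate_cohort(cohort_config(n_patients = 40, seed = 88))
  rows <- cohort_lag_features(sim$cohort)
  fit <- train_xgb(rows, xgb_config(seed = 2))
  rows$age <- 50 # constant across the test set: permutation is identity
  imp <- permutation_importance(fit, rows, seed = 4, n_repeats = 2)
  expect_equal(imp$delta_mse[imp$feature == "age"], 0)

  # planted signal: the empirical-alpha lag must dominate lab features
  imp_full <- permutation_importance(fit, cohort_lag_features(sim$cohort),
                                     seed = 4, n_repeats = 3)
  lab_best <- max(imp_full$delta_mse[grepl("haematocrit|albumin|alt|ast",
                                           imp_full$feature)])
  expect_gt(imp_full$delta_mse[imp_full$feature == "lag1_emp_alpha"],
            lab_best)
})

test_that("gain importance is a normalized share with planted-signal order", {
  sim <- simulate_cohort(cohort_config(n_patients = 60, seed = 99))
  rows <- cohort_lag_features(sim$cohort)
  fit <- train_xgb(rows, xgb_config(seed = 3))
  gi <- gain_importance(fit)
  expect_equal(sum(gi$gain_pct), 100, tolerance = 1e-6)
  expect_true(all(gi$gain_pct >= 0))
  expect_equal(gi$feature[1], "lag1_emp_alpha")

  # a model with a single usable feature concentrates all gain on it
  rows1 <- rows
  keep <- "lag1_emp_alpha"
  for (cl in setdiff(fit$feature_names, keep)) rows1[[cl]] <- 0
  fit1 <- train_xgb(rows1, xgb_config(seed = 3))
  gi1 <- gain_importance(fit1)
  expect_equal(gi1$gain_pct[gi1$feature == keep], 100, tolerance = 1e-6)
})
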