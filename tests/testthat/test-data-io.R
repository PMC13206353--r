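test_that("cohorts round-trip through the CSV writer and reader", {
  sim <- simulate_cohort(cohort_config(n_patients = 5, seed = 31))
  dir <- withr::local_tempdir()
  paths <- write_cohort(sim, dir)
  expect_true(all(file.exists(paths)))
  cohort <- read_cohort(paths["doses"], paths["troughs"], paths["labs"],
                        paths["static"])
  expect_length(cohort, length(sim$cohort))
  for (i in seq_along(cohort)) {
    expect_equal(cohort[[i]]$doses, sim$cohort[[i]]$doses,
                 tolerance = 1e-10)
    expect_equal(cohort[[i]]$troughs$conc_ng_ml,
                 sim$cohort[[i]]$troughs$conc_ng_ml, tolerance = 1e-10)
    expect_true(all(diff(cohort[[i]]$troughs$time_h) > 0))
  }
})

test_that("inclusion rules drop and log ineligible patients", {
  doses <- data.frame(patient_id = c("A", "A", "B", "B"),
                      time_h = c(0, 12, 0, 12), dose_mg = c(5, 5, 4, 4))
  troughs <- data.frame(patient_id = c("A", "A", "B"),
                        time_h = c(23.5, 47.5, 23.5),
                        conc_ng_ml = c(9, 11, 10))
  labs <- do.call(rbind, lapply(c("A", "B"), function(p) {
    do.call(rbind, lapply(c("haematocrit", "albumin", "alt", "ast",
                            "creatinine"), function(a) {
      data.frame(patient_id = p, analyte = a, time_h = 0, value = 30)
    }))
  }))
  static <- do.call(rbind, lapply(c("A", "B"), function(p) {
    data.frame(patient_id = p, age = 50, sex = "M", race = "Other",
               height_cm = 175, weight_kg = 80, bmi = 26.1, bsa = 1.97,
               smoking = 0, alcohol = 0, cyp3a_inhibitor = 0,
               cyp3a_inducer = 0)
  }))
  cohort <- read_cohort(doses, troughs, labs, static)
  expect_length(cohort, 1) # B has a single trough
  excl <- attr(cohort, "exclusions")
  expect_equal(excl$patient_id, "B")
  expect_match(excl$reason, "fewer than two")

  # causality: trough before the first dose is an error
  tr_bad <- troughs
  tr_bad$time_h[1] <- -2
  expect_error(read_cohort(doses, tr_bad, labs, static), "causality")

  # a trough at 30 h with first dose at 40 h
  d40 <- doses; d40$time_h <- d40$time_h + 40
  expect_error(read_cohort(d40, troughs, labs, static), "causality")

  # duplicated dose rows
  expect_error(read_cohort(rbind(doses, doses[1, ]), troughs, labs, static),
               "duplicated")
  # schema violation names the column
  expect_error(read_cohort(doses[, 1:2], troughs, labs, static), "dose_mg")
  # sub-LLOQ troughs dropped with a warning
  tr_low <- troughs
  tr_low$conc_ng_ml[2] <- 0.4
  expect_warning(cl <- read_cohort(doses, tr_low, labs, static),
                 "sub-LLOQ")
  expect_length(cl, 0) # A now has one quantifiable trough
})

test_that("lab imputation interpolates interior gaps and carries edges", {
  expect_equal(impute_labs(c(0, 48), c(30, 34), 24), 32)
  expect_equal(impute_labs(c(0, 48), c(30, 34), 60), 34)  # carried forward
  expect_equal(impute_labs(c(10, 48), c(30, 34), 0), 30)  # carried backward
  expect_equal(impute_labs(5, 28, c(0, 100)), c(28, 28))  # single point
  expect_error(impute_labs(numeric(0), numeric(0), 1), "empty")
})

test_that("static covariate encoding is deterministic, one-hot and z-scored", {
  s <- tiny_record()$static
  v1 <- encode_static(s)
  v2 <- encode_static(s)
  expect_identical(v1, v2)
  race_cols <- c("race_caucasian", "race_african_american", "race_other")
  expect_equal(sum(v1[race_cols]), 1)
  s$race <- "Other"
  expect_equal(unname(encode_static(s)[race_cols]), c(0, 0, 1))
  s$race <- "Martian"
  expect_error(encode_static(s), "unknown race")

  # a feature equal to the training mean maps to zero
  train <- do.call(rbind, lapply(tiny_cohort(4), `[[`, "static"))
  st <- fit_static_stats(train)
  s2 <- train[1, ]; s2$age <- mean(train$age)
  expect_equal(unname(encode_static(s2, st)["age"]), 0)
})

test_that("sequence construction yields nested histories, one per target", {
  rec <- tiny_record(trough_times = 23.5 + 24 * 0:5,
                     conc = c(9, 11, 10, 12, 9, 10))
  samples <- build_sequences(rec)
  expect_length(samples, 5) # six troughs -> five samples
  expect_length(build_sequences(tiny_record()), 1) # two troughs -> one
  for (k in seq_along(samples)) {
    expect_equal(nrow(samples[[k]]$features), k)
    expect_equal(samples[[k]]$target_index, k + 1L)
    # strictly nested prefixes
    if (k > 1) {
      expect_equal(samples[[k]]$features[seq_len(k - 1), , drop = FALSE],
                   samples[[k - 1]]$features)
    }
    # no information at or after the target time
    expect_true(all(samples[[k]]$features[, "t_h"] <
                      samples[[k]]$target_time))
    expect_true(all(samples[[k]]$doses$time_h <= samples[[k]]$target_time))
  }
  # the two sample builders agree on the count per patient
  expect_equal(length(samples), nrow(build_lag_features(rec)))
})

test_that("padding marks real steps and preserves the contents", {
  rec <- tiny_record(trough_times = 23.5 + 24 * 0:3, conc = c(9, 11, 10, 12))
  samples <- build_sequences(rec)
  pb <- pad_batch(samples)
  expect_equal(dim(pb$x)[2], 3)
  expect_equal(pb$lengths, 1:3)
  expect_equal(unname(rowSums(pb$mask)), 1:3)
  # padded positions are zero
  expect_true(all(pb$x[1, 2:3, ] == 0))
  # equal lengths -> all-true mask
  pb2 <- pad_batch(samples[c(2, 2)])
  expect_true(all(pb2$mask))
  expect_error(pad_batch(list()), "empty")
})

test_that("lag features encode the two most recent troughs with flags", {
  rec <- tiny_record(trough_times = c(23.5, 47.5, 71.5), conc = c(9, 11, 10))
  rows <- build_lag_features(rec, ke = 0.0578)
  expect_equal(nrow(rows), 2)
  expect_equal(rows$has_lag2, c(0, 1))
  expect_true(all(rows[1, grep("^lag2_", names(rows))] == 0))
  # time interval = target time minus previous trough time
  expect_equal(rows$dt_prev_trough_h, c(24, 24))
  expect_equal(rows$t_after_first_dose_h, c(47.5, 71.5))
  # the empirical alpha lag reproduces empirical_alpha at the lag-1 trough
  d1 <- rec$doses[rec$doses$time_h <= 23.5, ]
  expect_equal(rows$lag1_emp_alpha[1],
               empirical_alpha(9, d1, 23.5, 0.0578), tolerance = 1e-12)
  expect_equal(rows$lag1_remaining_mg[1],
               oracle_remaining(d1$time_h, d1$dose_mg, 23.5, 0.0578),
               tolerance = 1e-12)
  # daily dose: total mg in the 24 h before the target
  expect_equal(rows$daily_dose_mg[1], 12)

  # per-target ke vector is honoured
  rows2 <- build_lag_features(rec, ke = c(0.05, 0.08))
  expect_equal(rows2$ke_used, c(0.05, 0.08))
  expect_error(build_lag_features(rec, ke = c(0.05, 0.08, 0.1)), "scalar")
})
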