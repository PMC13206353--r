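make_samples <- function(n_patients = 6, seed = 3, prop_sd = 0.15) {
  sim <- simulate_cohort(cohort_config(n_patients = n_patients, seed = seed,
                                       prop_sd = prop_sd))
  cohort_sequences(sim$cohort)
}

test_that("backpropagation matches central finite differences", {
  s <- make_samples()
  for (mode in c("mechanism", "direct")) {
    cfg <- gru_config(hidden_size = 4, seed = 2, mode = mode)
    all_steps <- do.call(rbind, lapply(s, `[[`, "features"))
    sd <- apply(all_steps, 2, stats::sd); sd[sd == 0] <- 1
    norm <- list(mu = unname(colMeans(all_steps)), sd = unname(sd))
    set.seed(2)
    P <- tacdose:::gru_init_params(ncol(all_steps), cfg)
    pb <- tacdose:::gru_prepare(s, norm)
    fw <- tacdose:::gru_forward(P, pb, cfg, keep_cache = TRUE)
    g <- tacdose:::gru_backward(P, pb, cfg, fw)
    loss <- function(P) {
      mean((tacdose:::gru_forward(P, pb, cfg)$pred - pb$y)^2)
    }
    set.seed(5)
    for (nm in names(P)) {
      idx <- if (length(P[[nm]]) > 4) sample(length(P[[nm]]), 4)
             else seq_along(P[[nm]])
      for (i in idx) {
        e <- 1e-5
        Pp <- P; Pp[[nm]][i] <- Pp[[nm]][i] + e
        Pm <- P; Pm[[nm]][i] <- Pm[[nm]][i] - e
        fd <- (loss(Pp) - loss(Pm)) / (2 * e)
        expect_lt(abs(fd - g[[nm]][i]) / max(1e-8, abs(fd), abs(g[[nm]][i])),
                  1e-4)
      }
    }
  }
})

test_that("per-sample output is invariant to co-batched padding", {
  # guarantee ragged lengths by adding a hand-built four-trough patient
  s <- c(make_samples(10, seed = 8),
         build_sequences(tiny_record(trough_times = 23.5 + 24 * 0:3,
                                     conc = c(9, 11, 10, 12))))
  lens <- vapply(s, function(x) nrow(x$features), integer(1))
  expect_gt(max(lens), 1)
  fit <- train_gru(s, gru_config(max_epochs = 2, seed = 1))
  long <- s[[which.max(lens)]]
  short <- s[[which.min(lens)]]
  alone <- predict(fit, list(short))
  batched <- predict(fit, list(short, long))
  expect_lt(abs(alone$predicted - batched$predicted[1]), 1e-12)
  expect_lt(abs(alone$alpha - batched$alpha[1]), 1e-12)
  expect_lt(abs(alone$ke - batched$ke[1]), 1e-12)
})

test_that("training is deterministic given the seed and frozen at lr = 0", {
  s <- make_samples()
  f1 <- train_gru(s, gru_config(max_epochs = 3, seed = 11))
  f2 <- train_gru(s, gru_config(max_epochs = 3, seed = 11))
  expect_identical(f1$params, f2$params)
  expect_identical(f1$loss_history, f2$loss_history)

  f0 <- train_gru(s, gru_config(max_epochs = 3, seed = 11,
                                learning_rate = 0))
  set.seed(11)
  P_init <- tacdose:::gru_init_params(ncol(s[[1]]$features),
                                      gru_config(seed = 11))
  expect_identical(f0$params$Wz, P_init$Wz)
  expect_identical(f0$params$wa, P_init$wa)
})

test_that("the ke head is architecturally confined to its plausible range", {
  s <- make_samples(12, seed = 13)
  fit <- train_gru(s, gru_config(max_epochs = 2, seed = 4))
  # probe with extreme inputs, not just the training distribution
  extreme <- lapply(s, function(x) {
    x$features <- x$features * 50
    x
  })
  p <- predict(fit, c(s, extreme))
  expect_gte(min(p$ke), 0.017)
  expect_lte(max(p$ke), 0.17)
  expect_true(all(p$alpha > 0))

  pk <- gru_estimate_params(fit, s[[1]])
  expect_s3_class(pk, "pk_params")
  expect_equal(pk$alpha, p$alpha[1])
  expect_equal(pk$ke, p$ke[1])
})

test_that("a single noise-free patient can be fit to near zero error", {
  sim <- simulate_cohort(cohort_config(n_patients = 30, seed = 19,
                                       prop_sd = 0))
  counts <- vapply(sim$cohort, function(r) nrow(r$troughs), integer(1))
  rec <- sim$cohort[[which.max(counts)]]
  s <- build_sequences(rec)
  # paper-rate optimizer needs more than the capped epochs for a cold-start
  # overfit; a suitably larger lr reaches the floor within the cap
  fit <- train_gru(s, gru_config(max_epochs = 30, learning_rate = 0.05,
                                 batch_size = 1, seed = 6))
  expect_lt(tail(fit$loss_history, 1), 0.01)
})

test_that("mechanism predictions recompute exactly from the emitted parameters", {
  s <- make_samples(8, seed = 23)
  fit <- train_gru(s, gru_config(max_epochs = 3, seed = 9))
  p <- predict(fit, s)
  for (i in seq_along(s)) {
    recomputed <- p$alpha[i] * oracle_remaining(
      s[[i]]$doses$time_h, s[[i]]$doses$dose_mg, s[[i]]$target_time,
      p$ke[i])
    expect_equal(p$predicted[i], recomputed, tolerance = 1e-12)
  }
})

test_that("dose doubling doubles mechanism predictions at frozen parameters", {
  s <- make_samples(8, seed = 29)
  fitm <- train_gru(s, gru_config(max_epochs = 3, seed = 2))
  fitd <- train_gru(s, gru_config(max_epochs = 3, seed = 2,
                                  mode = "direct"))
  pm <- predict(fitm, s)
  # freeze parameters: scale only the superposition inputs
  s2 <- lapply(s, function(x) {
    x$doses$dose_mg <- 2 * x$doses$dose_mg
    x
  })
  pm2 <- vapply(seq_along(s2), function(i) {
    pm$alpha[i] * remaining_amount(s2[[i]]$doses, s2[[i]]$target_time,
                                   pm$ke[i])
  }, numeric(1))
  expect_equal(pm2, 2 * pm$predicted, tolerance = 1e-9)

  # zero-dose counterfactual
  s0 <- lapply(s, function(x) { x$doses <- dose_events(); x })
  p0 <- vapply(seq_along(s0), function(i) {
    pm$alpha[i] * remaining_amount(s0[[i]]$doses, s0[[i]]$target_time,
                                   pm$ke[i])
  }, numeric(1))
  expect_true(all(p0 == 0))

  # the data-driven ablation carries no such guarantee: deviation is
  # recorded, not asserted
  pd <- predict(fitd, s)
  s2f <- lapply(s, function(x) {
    x$features[, "dose_mg_since_prev"] <- 2 * x$features[, "dose_mg_since_prev"]
    x$doses$dose_mg <- 2 * x$doses$dose_mg
    x
  })
  pd2 <- predict(fitd, s2f)
  deviation <- abs(pd2$predicted / pd$predicted - 2)
  expect_true(is.numeric(deviation)) # interface contract only
})

test_that("non-finite losses abort with diagnostics", {
  s <- make_samples(4, seed = 1)
  s[[1]]$target_conc <- Inf
  expect_error(train_gru(s, gru_config(max_epochs = 1, seed = 1)),
               "non-finite training loss")
})
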