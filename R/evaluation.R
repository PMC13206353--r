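# Patient-level stratified cross-validation, the trough-forecasting metric
# suite, target-attainment stratification and feature importance.

#' Trough-forecasting metric suite
#'
#' MSE, MAE, R2 (1 - SSE/SST), MPE = 100 mean((pred - obs)/obs) (positive =
#' overprediction), RMSRPE = 100 sqrt(mean(((pred - obs)/obs)^2)) and
#' P10/P20/P30 = percentage of predictions within +/-10/20/30 percent of the
#' observed value.
#'
#' @param observed Observed troughs, ng/mL (all > 0).
#' @param predicted Predicted troughs, ng/mL.
#' @return One-row data.frame: mse, mae, r2, mpe, rmsrpe, p10, p20, p30, n.
#'   With n = 1, r2 is NA.
#' @export
compute_metrics <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 1)
  if (any(!is.finite(observed)) || any(observed <= 0)) {
    stop("observed troughs must be positive for the relative metrics")
  }
  e <- predicted - observed
  rel <- e / observed
  sst <- sum((observed - mean(observed))^2)
  data.frame(
    mse = mean(e^2),
    mae = mean(abs(e)),
    r2 = if (length(observed) > 1 && sst > 0) 1 - sum(e^2) / sst else NA_real_,
    mpe = 100 * mean(rel),
    rmsrpe = 100 * sqrt(mean(rel^2)),
    p10 = 100 * mean(abs(rel) <= 0.10),
    p20 = 100 * mean(abs(rel) <= 0.20),
    p30 = 100 * mean(abs(rel) <= 0.30),
    n = length(observed)
  )
}

#' Patient-level stratified fold assignment
#'
#' Every patient lands in exactly one fold. Assignment is stratified on
#' per-patient trough-count bins (2, 3, >= 4) so fold difficulty is balanced;
#' within a bin patients are shuffled (seeded) and dealt round-robin.
#'
#' @param cohort A `tac_cohort`.
#' @param k Number of folds.
#' @param seed Seed; the assignment is deterministic given it.
#' @return Named integer vector patient_id -> fold (1..k).
#' @export
make_folds <- function(cohort, k = 5, seed = 1L) {
  stopifnot(inherits(cohort, "tac_cohort"))
  ids <- vapply(cohort, `[[`, "", "patient_id")
  if (k > length(ids)) stop("k = ", k, " exceeds ", length(ids), " patients")
  nt <- vapply(cohort, function(r) nrow(r$troughs), integer(1))
  bin <- cut(nt, c(1, 2, 3, Inf), labels = c("2", "3", "4+"))
  set.seed(seed)
  fold <- integer(length(ids))
  offset <- 0L
  for (b in levels(bin)) {
    i <- which(bin == b)
    if (!length(i)) next
    fold[i[sample.int(length(i))]] <-
      ((offset + seq_along(i) - 1L) %% k) + 1L
    offset <- offset + length(i)
  }
  stats::setNames(fold, ids)
}

#' Patient-level cross-validation of a trough model
#'
#' Trains on k-1 folds and evaluates on the held-out fold, for each fold.
#' Both fold-averaged and pooled-prediction metrics are reported. The
#' Bayesian forecaster has no trainable weights here (fixed prior), so its
#' forecasts are simply evaluated per fold under the same protocol.
#'
#' @param cohort A `tac_cohort`.
#' @param model One of `"gru_mech"`, `"gru_dd"`, `"xgb_mech"`, `"xgb_dd"`,
#'   `"bayes"`.
#' @param k Number of outer folds.
#' @param seed Seed driving fold assignment and model seeds.
#' @param gru_cfg,xgb_cfg,prior Model configurations; defaults used when
#'   omitted (the `mode` field is set from `model`).
#' @param ke Passed to [cohort_lag_features()] for the boosted models.
#' @return List: `predictions` (pooled data.frame with fold column),
#'   `pooled` (metrics on all held-out predictions), `per_fold` (metrics by
#'   fold), `fold_mean` (mean of the per-fold metrics).
#' @export
crossvalidate <- function(cohort, model = "gru_mech", k = 5, seed = 1L,
                          gru_cfg = NULL, xgb_cfg = NULL,
                          prior = pop_prior(), ke = 0.0578) {
  stopifnot(model %in% c("gru_mech", "gru_dd", "xgb_mech", "xgb_dd", "bayes"))
  folds <- make_folds(cohort, k, seed)
  ids <- vapply(cohort, `[[`, "", "patient_id")

  if (model %in% c("gru_mech", "gru_dd")) {
    if (is.null(gru_cfg)) {
      gru_cfg <- gru_config(mode = if (model == "gru_mech") "mechanism"
                            else "direct", seed = seed)
    }
    samples <- cohort_sequences(cohort)
    spid <- vapply(samples, `[[`, "", "patient_id")
    preds <- lapply(sort(unique(folds)), function(f) {
      test_pat <- names(folds)[folds == f]
      fit <- train_gru(samples[!spid %in% test_pat], gru_cfg)
      p <- predict(fit, samples[spid %in% test_pat])
      p$fold <- f
      p
    })
    predictions <- do.call(rbind, preds)
  } else if (model %in% c("xgb_mech", "xgb_dd")) {
    if (is.null(xgb_cfg)) {
      xgb_cfg <- xgb_config(mode = if (model == "xgb_mech") "mechanism"
                            else "direct", seed = seed)
    }
    rows <- cohort_lag_features(cohort, ke)
    predictions <- train_xgb_nested_cv(rows, xgb_cfg, folds)$predictions
  } else {
    predictions <- bayes_forecast_cohort(cohort, prior)
    predictions$fold <- folds[predictions$patient_id]
  }
  predictions$model <- model

  per_fold <- do.call(rbind, lapply(sort(unique(predictions$fold)),
                                    function(f) {
    m <- compute_metrics(predictions$observed[predictions$fold == f],
                         predictions$predicted[predictions$fold == f])
    cbind(fold = f, m)
  }))
  pooled <- compute_metrics(predictions$observed, predictions$predicted)
  fold_mean <- as.data.frame(t(colMeans(per_fold[setdiff(names(per_fold),
                                                         "fold")])))
  list(predictions = predictions, pooled = pooled, per_fold = per_fold,
       fold_mean = fold_mean)
}

#' Target-attainment table stratified by dose-recommendation agreement
#'
#' For the strata all / within / below / above the model-recommended dose
#' range (and `no_recommendation` when the admissible set was empty), the
#' percentage of subsequent observed troughs below, inside and above the
#' therapeutic window (closed on both ends), plus a per-measurement-index
#' trend of within-target percentages.
#'
#' @param decisions data.frame with columns `observed` (the next trough,
#'   ng/mL), `category` (from [recommend_range_check()]) and `target_index`.
#' @param target Therapeutic window, ng/mL.
#' @return List with `by_stratum` and `by_index` data.frames.
#' @export
target_attainment <- function(decisions, target = c(8, 12)) {
  classify <- function(x) {
    ifelse(x < target[1], "below_target",
           ifelse(x > target[2], "above_target", "within_target"))
  }
  decisions$tclass <- classify(decisions$observed)
  strata <- list(all = rep(TRUE, nrow(decisions)),
                 within = decisions$category == "within",
                 below = decisions$category == "below",
                 above = decisions$category == "above")
  by_stratum <- do.call(rbind, lapply(names(strata), function(s) {
    d <- decisions[strata[[s]], , drop = FALSE]
    if (!nrow(d)) {
      return(data.frame(stratum = s, n = 0L, pct_below = NA_real_,
                        pct_within = NA_real_, pct_above = NA_real_))
    }
    data.frame(stratum = s, n = nrow(d),
               pct_below = 100 * mean(d$tclass == "below_target"),
               pct_within = 100 * mean(d$tclass == "within_target"),
               pct_above = 100 * mean(d$tclass == "above_target"))
  }))
  by_index <- do.call(rbind, lapply(sort(unique(decisions$target_index)),
                                    function(i) {
    d <- decisions[decisions$target_index == i, , drop = FALSE]
    w <- d[d$category == "within", , drop = FALSE]
    data.frame(target_index = i, n_all = nrow(d),
               pct_within_all = 100 * mean(d$tclass == "within_target"),
               n_within_rec = nrow(w),
               pct_within_rec = if (nrow(w)) {
                 100 * mean(w$tclass == "within_target")
               } else NA_real_)
  }))
  list(by_stratum = by_stratum, by_index = by_index)
}

#' Chi-square test of attainment between strata (convenience)
#'
#' @param decisions As in [target_attainment()].
#' @param target Therapeutic window.
#' @return `htest` from [stats::chisq.test()] comparing within-window rates
#'   for doses within vs outside the recommended range.
#' @export
attainment_test <- function(decisions, target = c(8, 12)) {
  inside <- decisions$observed >= target[1] & decisions$observed <= target[2]
  grp <- ifelse(decisions$category == "within", "within_rec", "outside_rec")
  stats::chisq.test(table(grp, inside))
}

#' Permutation feature importance
#'
#' Each feature is shuffled across the test set (10 seeded repeats by
#' default) and the increase in trough MSE over the unpermuted baseline is
#' averaged. For sequence models the feature's values are permuted across
#' the pooled valid (sample, step) positions; for row models the column is
#' permuted across rows.
#'
#' @param fit A `gru_fit` or `xgb_fit`.
#' @param data Test sequence samples (list) or lag-feature rows (data.frame).
#' @param seed Seed.
#' @param n_repeats Permutation repeats per feature.
#' @return data.frame with `feature` and `delta_mse`, sorted decreasing.
#' @export
permutation_importance <- function(fit, data, seed = 1L, n_repeats = 10) {
  base <- predict(fit, data)
  base_mse <- mean((base$predicted - base$observed)^2)
  feats <- fit$feature_names
  set.seed(seed)
  delta <- vapply(feats, function(f) {
    mean(vapply(seq_len(n_repeats), function(r) {
      perm <- data
      if (is.data.frame(data)) {
        perm[[f]] <- sample(perm[[f]])
      } else {
        j <- match(f, colnames(data[[1]]$features))
        pool <- unlist(lapply(perm, function(s) s$features[, j]))
        pool <- sample(pool)
        at <- 0L
        for (i in seq_along(perm)) {
          ni <- nrow(perm[[i]]$features)
          perm[[i]]$features[, j] <- pool[at + seq_len(ni)]
          at <- at + ni
        }
      }
      p <- predict(fit, perm)
      mean((p$predicted - p$observed)^2) - base_mse
    }, numeric(1)))
  }, numeric(1))
  out <- data.frame(feature = feats, delta_mse = unname(delta))
  out[order(-out$delta_mse), ]
}

#' Gain-based feature importance for a boosted model
#'
#' @param fit An `xgb_fit`.
#' @return data.frame with `feature` and `gain_pct` (non-negative, summing
#'   to 100); features never used by a split get 0.
#' @export
gain_importance <- function(fit) {
  stopifnot(inherits(fit, "xgb_fit"))
  imp <- xgboost::xgb.importance(model = fit$booster)
  gain <- stats::setNames(rep(0, length(fit$feature_names)),
                          fit$feature_names)
  gain[imp$Feature] <- imp$Gain
  data.frame(feature = names(gain),
             gain_pct = 100 * as.numeric(gain) / sum(gain))[
               order(-gain), ]
}
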