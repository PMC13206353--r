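# Gradient-boosted trough models over lag features. The mechanism-informed
# variant predicts the composite exposure parameter alpha from the lag
# features (remaining drug amount, observed trough and empirical alpha at the
# two most recent TDM measurements, labs, time features, static covariates)
# and converts it to a trough through the superposition term
# C_hat = alpha_hat * remaining_amount(target time), with ke fixed at a
# population value (0.0578 1/h) or supplied per patient. The purely
# data-driven ablation drops the drug-amount and empirical-alpha lags,
# adds the daily dose, and predicts the trough directly.
# Hyperparameters are tuned by an inner four-fold patient-level CV nested in
# the outer evaluation folds.

.mech_drop <- c("target_remaining_mg", "target_conc", "target_index",
                "patient_id", "ke_used", "daily_dose_mg")
.dd_drop <- c("target_remaining_mg", "target_conc", "target_index",
              "patient_id", "ke_used",
              "lag1_remaining_mg", "lag1_emp_alpha",
              "lag2_remaining_mg", "lag2_emp_alpha")

xgb_feature_names <- function(rows, mode) {
  setdiff(names(rows), if (mode == "mechanism") .mech_drop else .dd_drop)
}

#' Configuration for the boosted trough models
#'
#' @param grid Data frame of candidate hyperparameters (columns `max_depth`,
#'   `eta`, `nrounds`, `subsample`) searched by the inner CV.
#' @param ke_mode `"fixed_population"` (ke = `fixed_ke` everywhere) or
#'   `"per_patient"` (rows were built with individual ke estimates).
#' @param fixed_ke Population elimination rate constant, 1/h.
#' @param mode `"mechanism"` (predict alpha, convert via remaining amount) or
#'   `"direct"` (predict the trough).
#' @param inner_folds Inner CV folds for hyperparameter tuning.
#' @param seed Seed for fold assignment and subsampling.
#' @return List of class `xgb_config`.
#' @export
xgb_config <- function(grid = expand.grid(max_depth = c(2L, 3L),
                                          eta = c(0.1, 0.3),
                                          nrounds = 150L,
                                          subsample = 0.8),
                       ke_mode = c("fixed_population", "per_patient"),
                       fixed_ke = 0.0578,
                       mode = c("mechanism", "direct"),
                       inner_folds = 4L,
                       seed = 1L) {
  ke_mode <- match.arg(ke_mode)
  mode <- match.arg(mode)
  stopifnot(nrow(grid) >= 1, fixed_ke > 0, fixed_ke < 1, inner_folds >= 2)
  structure(list(grid = grid, ke_mode = ke_mode, fixed_ke = fixed_ke,
                 mode = mode, inner_folds = as.integer(inner_folds),
                 seed = as.integer(seed)),
            class = "xgb_config")
}

xgb_label <- function(rows, mode) {
  if (mode == "mechanism") rows$target_conc / rows$target_remaining_mg
  else rows$target_conc
}

#' Train a single boosted model on lag-feature rows
#'
#' @param rows Output of [cohort_lag_features()] (training rows only).
#' @param cfg An [xgb_config()].
#' @param hyper One row of the hyperparameter grid (default: first row).
#' @return Object of class `xgb_fit`.
#' @export
train_xgb <- function(rows, cfg = xgb_config(), hyper = cfg$grid[1, ]) {
  feats <- xgb_feature_names(rows, cfg$mode)
  x <- as.matrix(rows[, feats, drop = FALSE])
  y <- xgb_label(rows, cfg$mode)
  set.seed(cfg$seed)
  booster <- xgboost::xgb.train(
    params = list(max_depth = hyper$max_depth, eta = hyper$eta,
                  subsample = hyper$subsample,
                  objective = "reg:squarederror", nthread = 1,
                  seed = cfg$seed),
    data = xgboost::xgb.DMatrix(x, label = y),
    nrounds = hyper$nrounds, verbose = 0
  )
  structure(list(booster = booster, config = cfg, hyper = hyper,
                 feature_names = feats, schema_version = 1L),
            class = "xgb_fit")
}

#' Predict troughs (and alpha) for lag-feature rows
#'
#' In mechanism mode the predicted alpha is floored at a small positive value
#' (alpha <= 0 is physically meaningless) and the trough is
#' alpha_hat * remaining drug amount at the target time.
#'
#' @param object An `xgb_fit`.
#' @param rows Lag-feature rows.
#' @param ... Unused.
#' @return data.frame: patient_id, target_index, observed, predicted, and in
#'   mechanism mode alpha.
#' @export
predict.xgb_fit <- function(object, rows, ...) {
  x <- as.matrix(rows[, object$feature_names, drop = FALSE])
  raw <- stats::predict(object$booster, xgboost::xgb.DMatrix(x))
  out <- data.frame(patient_id = rows$patient_id,
                    target_index = rows$target_index,
                    observed = rows$target_conc)
  if (object$config$mode == "mechanism") {
    if (any(rows$target_remaining_mg <= 0)) {
      stop("non-positive remaining drug amount at a target time")
    }
    out$alpha <- pmax(raw, 1e-6)
    out$predicted <- out$alpha * rows$target_remaining_mg
  } else {
    out$predicted <- pmax(raw, 0)
  }
  out
}

#' @rdname predict.xgb_fit
#' @export
xgb_predict_trough <- function(object, rows) predict(object, rows)

# Patient-level k-fold assignment of a vector of patient ids.
split_patients <- function(ids, k, seed) {
  u <- unique(ids)
  if (length(u) < k) stop("fewer patients (", length(u), ") than folds ", k)
  set.seed(seed)
  f <- stats::setNames(rep(seq_len(k), length.out = length(u))[sample.int(length(u))], u)
  f
}

#' Nested cross-validation for the boosted models
#'
#' For each outer fold: an inner four-fold patient-level CV over the
#' hyperparameter grid selects the setting with the lowest mean inner trough
#' MSE; the winner is refit on the full outer-training set and evaluated once
#' on the outer-test fold. A patient appearing in more than one outer fold is
#' an error (leakage).
#'
#' @param rows Lag-feature rows for the whole cohort.
#' @param cfg An [xgb_config()].
#' @param outer_folds Named vector mapping patient_id to outer fold index
#'   (e.g. from [make_folds()]).
#' @return List with `predictions` (pooled outer-test predictions with a
#'   `fold` column), `fits` and `chosen` (per-fold hyperparameters).
#' @export
train_xgb_nested_cv <- function(rows, cfg = xgb_config(), outer_folds) {
  if (anyDuplicated(names(outer_folds))) {
    stop("a patient appears in more than one outer fold (leakage)")
  }
  if (!all(rows$patient_id %in% names(outer_folds))) {
    stop("rows contain patients without an outer-fold assignment")
  }
  ks <- sort(unique(outer_folds))
  fits <- list(); chosen <- list(); preds <- list()
  for (k in ks) {
    test_pat <- names(outer_folds)[outer_folds == k]
    train_rows <- rows[!rows$patient_id %in% test_pat, , drop = FALSE]
    test_rows <- rows[rows$patient_id %in% test_pat, , drop = FALSE]
    stopifnot(!any(test_rows$patient_id %in% train_rows$patient_id))

    inner <- split_patients(train_rows$patient_id, cfg$inner_folds,
                            seed = cfg$seed + k)
    stopifnot(!any(names(inner) %in% test_pat))
    score <- vapply(seq_len(nrow(cfg$grid)), function(g) {
      mean(vapply(seq_len(cfg$inner_folds), function(j) {
        val_pat <- names(inner)[inner == j]
        fit <- train_xgb(
          train_rows[!train_rows$patient_id %in% val_pat, , drop = FALSE],
          cfg, cfg$grid[g, ])
        p <- predict(fit,
                     train_rows[train_rows$patient_id %in% val_pat, ,
                                drop = FALSE])
        mean((p$predicted - p$observed)^2)
      }, numeric(1)))
    }, numeric(1))
    best <- cfg$grid[which.min(score), ]
    fit <- train_xgb(train_rows, cfg, best)
    p <- predict(fit, test_rows)
    p$fold <- k
    fits[[as.character(k)]] <- fit
    chosen[[as.character(k)]] <- cbind(best, inner_mse = min(score))
    preds[[as.character(k)]] <- p
  }
  list(predictions = do.call(rbind, preds), fits = fits,
       chosen = do.call(rbind, chosen))
}
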