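# Reading/validating patient tables, lab imputation, covariate encoding, and
# construction of the sequential windows (recurrent model) and lag-feature
# rows (boosted model).
#
# CSV schemas (all times are decimal hours since the first tacrolimus dose):
#   doses.csv:   patient_id, time_h, dose_mg
#   troughs.csv: patient_id, time_h, conc_ng_ml
#   labs.csv:    patient_id, analyte, time_h, value
#   static.csv:  patient_id, age, sex, race, height_cm, weight_kg, bmi, bsa,
#                smoking, alcohol, cyp3a_inhibitor, cyp3a_inducer

.analytes <- c("haematocrit", "albumin", "alt", "ast", "creatinine")
.races <- c("Caucasian", "African American", "Other")
.static_cols <- c("age", "sex", "race", "height_cm", "weight_kg", "bmi",
                  "bsa", "smoking", "alcohol", "cyp3a_inhibitor",
                  "cyp3a_inducer")

read_table_arg <- function(x, what) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("file not found: ", x)
    x <- utils::read.csv(x, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(x)) stop(what, " must be a data.frame or CSV path")
  x
}

require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop("schema violation in ", what, ": missing column(s) ",
         paste(miss, collapse = ", "))
  }
}

#' Read and validate a patient cohort
#'
#' Applies the inclusion rules: sub-LLOQ troughs are dropped with a warning,
#' patients with fewer than two quantifiable troughs are excluded (reason
#' logged in the `exclusions` attribute), every trough must be preceded by at
#' least one dose, and all event times must fall inside the observation
#' window. Duplicated (patient, time) dose rows are an error.
#'
#' @param doses,troughs,labs,static Data frames or CSV paths matching the
#'   schemas above.
#' @param window_hours Observation window, h.
#' @param lloq Lower limit of quantification, ng/mL.
#' @return A `tac_cohort`: a list of patient records, each with elements
#'   `patient_id`, `doses`, `troughs`, `labs`, `static`. Attribute
#'   `exclusions` is a data.frame of dropped patients and reasons.
#' @export
read_cohort <- function(doses, troughs, labs, static,
                        window_hours = 168, lloq = 1.0) {
  doses <- read_table_arg(doses, "doses")
  troughs <- read_table_arg(troughs, "troughs")
  labs <- read_table_arg(labs, "labs")
  static <- read_table_arg(static, "static")
  require_cols(doses, c("patient_id", "time_h", "dose_mg"), "doses")
  require_cols(troughs, c("patient_id", "time_h", "conc_ng_ml"), "troughs")
  require_cols(labs, c("patient_id", "analyte", "time_h", "value"), "labs")
  require_cols(static, c("patient_id", .static_cols), "static")
  if (anyDuplicated(static$patient_id)) stop("duplicated patient_id in static")
  if (anyDuplicated(doses[c("patient_id", "time_h")])) {
    stop("duplicated (patient_id, time_h) dose rows")
  }

  records <- list()
  excl <- list()
  for (pid in static$patient_id) {
    d <- doses[doses$patient_id == pid, , drop = FALSE]
    tr <- troughs[troughs$patient_id == pid, , drop = FALSE]
    lb <- labs[labs$patient_id == pid, , drop = FALSE]
    st <- static[static$patient_id == pid, , drop = FALSE]
    if (!st$race %in% .races) {
      stop("unknown race level '", st$race, "' for patient ", pid)
    }
    if (!nrow(d)) { excl[[pid]] <- "no doses"; next }
    dd <- dose_events(d$time_h, d$dose_mg)
    if (any(!is.finite(tr$conc_ng_ml))) {
      stop("non-finite trough concentration for patient ", pid)
    }
    if (nrow(tr) && any(tr$time_h <= min(dd$time_h))) {
      stop("trough before any dose for patient ", pid,
           " (causality violation)")
    }
    if (any(dd$time_h > window_hours) ||
        (nrow(tr) && any(tr$time_h > window_hours))) {
      stop("event beyond the ", window_hours, " h window for patient ", pid)
    }
    sub <- tr$conc_ng_ml < lloq
    if (any(sub)) {
      warning(sum(sub), " sub-LLOQ trough(s) dropped for patient ", pid)
      tr <- tr[!sub, , drop = FALSE]
    }
    if (nrow(tr) < 2) {
      excl[[pid]] <- "fewer than two quantifiable troughs"
      next
    }
    tr <- tr[order(tr$time_h), , drop = FALSE]
    if (anyDuplicated(tr$time_h)) {
      stop("duplicated trough times for patient ", pid)
    }
    lb <- lb[order(lb$analyte, lb$time_h), , drop = FALSE]
    rownames(tr) <- rownames(lb) <- NULL
    records[[pid]] <- list(patient_id = pid, doses = dd, troughs = tr,
                           labs = lb, static = st)
  }
  exclusions <- data.frame(patient_id = names(excl),
                           reason = unlist(excl, use.names = FALSE),
                           stringsAsFactors = FALSE)
  structure(unname(records), class = "tac_cohort", exclusions = exclusions)
}

#' Write a cohort to the four CSV tables
#'
#' @param x A `tac_cohort` or `tac_sim`; for a `tac_sim` the ground truth is
#'   written alongside as `ground_truth.csv`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(x, dir) {
  truth <- NULL
  if (inherits(x, "tac_sim")) { truth <- x$truth; x <- x$cohort }
  stopifnot(inherits(x, "tac_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grab <- function(field, keep) {
    do.call(rbind, lapply(x, function(r) {
      df <- r[[field]]
      cbind(patient_id = r$patient_id, df[, keep, drop = FALSE])
    }))
  }
  paths <- c(doses = file.path(dir, "doses.csv"),
             troughs = file.path(dir, "troughs.csv"),
             labs = file.path(dir, "labs.csv"),
             static = file.path(dir, "static.csv"))
  utils::write.csv(grab("doses", c("time_h", "dose_mg")), paths["doses"],
                   row.names = FALSE)
  utils::write.csv(grab("troughs", c("time_h", "conc_ng_ml")),
                   paths["troughs"], row.names = FALSE)
  utils::write.csv(grab("labs", c("analyte", "time_h", "value")),
                   paths["labs"], row.names = FALSE)
  static <- do.call(rbind, lapply(x, function(r) {
    r$static[, c("patient_id", .static_cols), drop = FALSE]
  }))
  utils::write.csv(static, paths["static"], row.names = FALSE)
  if (!is.null(truth)) {
    p <- file.path(dir, "ground_truth.csv")
    utils::write.csv(truth, p, row.names = FALSE)
    paths <- c(paths, ground_truth = p)
  }
  invisible(paths)
}

#' Impute a laboratory series at query times
#'
#' Interior gaps are linearly interpolated between adjacent observations;
#' queries beyond the observed range carry the nearest value forward or
#' backward.
#'
#' @param time_h,value Observed series (>= 1 point, sorted or not).
#' @param query_times Times at which values are needed, h.
#' @return Numeric vector of imputed values.
#' @export
impute_labs <- function(time_h, value, query_times) {
  ok <- is.finite(time_h) & is.finite(value)
  time_h <- time_h[ok]; value <- value[ok]
  if (!length(time_h)) stop("empty laboratory series")
  if (length(time_h) == 1) return(rep(value, length(query_times)))
  stats::approx(time_h, value, xout = query_times, method = "linear",
                rule = 2, ties = mean)$y
}

# 5 x length(t) matrix of imputed lab values for one patient
lab_values_at <- function(labs, t) {
  vapply(.analytes, function(a) {
    s <- labs[labs$analyte == a, , drop = FALSE]
    if (!nrow(s)) stop("missing laboratory analyte '", a, "'")
    impute_labs(s$time_h, s$value, t)
  }, numeric(length(t)))
}

#' Fit z-scoring statistics for continuous static covariates
#'
#' Means and SDs must come from training-fold patients only.
#'
#' @param static_df Rows of static covariates (training patients).
#' @return A list of means and SDs for the continuous fields.
#' @export
fit_static_stats <- function(static_df) {
  cont <- c("age", "height_cm", "weight_kg", "bmi", "bsa")
  mu <- vapply(cont, function(c) mean(static_df[[c]]), numeric(1))
  sd <- vapply(cont, function(c) {
    s <- stats::sd(static_df[[c]])
    if (!is.finite(s) || s == 0) 1 else s
  }, numeric(1))
  list(mu = mu, sd = sd)
}

#' Encode static covariates as a numeric vector
#'
#' One-hot race (3 columns), binary sex/smoking/alcohol/CYP3A flags, and
#' continuous fields z-scored with training-fold statistics when `stats` is
#' supplied (raw otherwise).
#'
#' @param s One-row data.frame of static covariates.
#' @param stats Optional output of [fit_static_stats()].
#' @return Named numeric vector (length 13).
#' @export
encode_static <- function(s, stats = NULL) {
  if (!s$race %in% .races) stop("unknown race level '", s$race, "'")
  cont <- c(age = s$age, height_cm = s$height_cm, weight_kg = s$weight_kg,
            bmi = s$bmi, bsa = s$bsa)
  if (!is.null(stats)) cont <- (cont - stats$mu) / stats$sd
  c(cont,
    sex_m = as.numeric(s$sex == "M"),
    race_caucasian = as.numeric(s$race == "Caucasian"),
    race_african_american = as.numeric(s$race == "African American"),
    race_other = as.numeric(s$race == "Other"),
    smoking = as.numeric(s$smoking), alcohol = as.numeric(s$alcohol),
    cyp3a_inhibitor = as.numeric(s$cyp3a_inhibitor),
    cyp3a_inducer = as.numeric(s$cyp3a_inducer))
}

.seq_step_names <- c("dose_mg_since_prev", "log_conc", "dt_prev_h",
                     "t_h", "log_remaining_mg", "log_emp_alpha", .analytes)

#' Build prediction-window sequence samples for one patient
#'
#' For each trough after the first, one sample whose history is all prior
#' troughs (strictly nested prefixes) and whose target is the next trough.
#' Per-step features: total dose administered since the previous step (mg),
#' the observed trough, time since previous step, time since first dose, the
#' remaining drug amount at the step's trough time and the empirical alpha
#' (both at the population ke, so they use only information available at the
#' step), and the five time-varying labs imputed at the trough time; the
#' static encoding is concatenated at every step. The trough, remaining
#' amount and empirical alpha enter in log scale: pharmacokinetic
#' variability is multiplicative (log-normal), so the optimal estimator is
#' close to linear in the logs. Dose events up to the target time are
#' attached so the superposition equation can be evaluated at the target.
#'
#' @param record One patient record from a `tac_cohort`.
#' @param ke_feat Population elimination rate constant used for the two
#'   mechanism-derived step features, 1/h.
#' @return List of sequence samples: `patient_id`, `target_index` (1-based
#'   chronological trough index), `features` (steps x features matrix),
#'   `target_time`, `target_conc`, `doses` (dose table up to target time).
#' @export
build_sequences <- function(record, ke_feat = 0.0578) {
  tr <- record$troughs
  n <- nrow(tr)
  if (n < 2) stop("patient ", record$patient_id, " has < 2 troughs")
  labs <- lab_values_at(record$labs, tr$time_h)
  static_vec <- encode_static(record$static)
  prev_t <- c(0, tr$time_h[-n])
  dose_since <- vapply(seq_len(n), function(k) {
    lo <- if (k == 1) -Inf else tr$time_h[k - 1]
    sum(record$doses$dose_mg[record$doses$time_h > lo &
                               record$doses$time_h <= tr$time_h[k]])
  }, numeric(1))
  rem <- vapply(seq_len(n), function(k) {
    remaining_amount(record$doses[record$doses$time_h <= tr$time_h[k], ,
                                  drop = FALSE], tr$time_h[k], ke_feat)
  }, numeric(1))
  steps <- cbind(dose_mg_since_prev = dose_since,
                 log_conc = log(tr$conc_ng_ml),
                 dt_prev_h = tr$time_h - prev_t,
                 t_h = tr$time_h,
                 log_remaining_mg = log(rem),
                 log_emp_alpha = log(tr$conc_ng_ml / rem),
                 labs)
  lapply(seq_len(n - 1), function(k) {
    feat <- cbind(steps[seq_len(k), , drop = FALSE],
                  matrix(static_vec, nrow = k, ncol = length(static_vec),
                         byrow = TRUE,
                         dimnames = list(NULL, names(static_vec))))
    list(patient_id = record$patient_id,
         target_index = k + 1L,
         features = feat,
         target_time = tr$time_h[k + 1],
         target_conc = tr$conc_ng_ml[k + 1],
         doses = record$doses[record$doses$time_h <= tr$time_h[k + 1], ,
                              drop = FALSE])
  })
}

#' Sequence samples for a whole cohort
#' @param cohort A `tac_cohort`.
#' @param ke_feat Population ke for the mechanism-derived step features, 1/h.
#' @return Flat list of sequence samples.
#' @export
cohort_sequences <- function(cohort, ke_feat = 0.0578) {
  stopifnot(inherits(cohort, "tac_cohort"))
  unlist(lapply(cohort, build_sequences, ke_feat = ke_feat),
         recursive = FALSE)
}

#' Zero-pad a batch of sequence samples
#'
#' All sequences are padded to the longest length in the batch; the mask
#' marks real steps. Models must give identical per-sample output whatever
#' the co-batched padding (the recurrent state carries through masked steps).
#'
#' @param samples Non-empty list of sequence samples.
#' @return List with `x` (n x T x d array, zero-padded), `mask`
#'   (n x T logical), `lengths`.
#' @export
pad_batch <- function(samples) {
  if (!length(samples)) stop("empty batch")
  lens <- vapply(samples, function(s) nrow(s$features), integer(1))
  Tmax <- max(lens)
  d <- ncol(samples[[1]]$features)
  x <- array(0, dim = c(length(samples), Tmax, d))
  mask <- matrix(FALSE, length(samples), Tmax)
  for (i in seq_along(samples)) {
    x[i, seq_len(lens[i]), ] <- samples[[i]]$features
    mask[i, seq_len(lens[i])] <- TRUE
  }
  list(x = x, mask = mask, lengths = lens)
}

#' Build lag-feature rows for the boosted models (one patient)
#'
#' One row per target trough (the first trough is never a target). The lag-1
#' and lag-2 blocks hold, at the two most recent prior troughs: the remaining
#' drug amount (mg, at the supplied ke), the observed concentration, the
#' empirical alpha (ratio of the two), and the five labs. When only one prior
#' trough exists the lag-2 block is zero-filled and `has_lag2` is 0. Time
#' features: time after transplantation, time after first dose and the
#' interval since the previous trough (transplantation is taken at the first
#' dose unless `static$transplant_offset_h` says otherwise). `daily_dose_mg`
#' (total mg in the 24 h before the target) serves the data-driven ablation.
#' `target_remaining_mg` is carried as metadata for the alpha -> trough
#' conversion, not as a predictor.
#'
#' @param record One patient record.
#' @param ke Elimination rate constant used for the drug-amount features,
#'   1/h: either one value (population default 0.0578) or a vector with one
#'   individual estimate per target trough (indices 2..n).
#' @return data.frame, one row per target.
#' @export
build_lag_features <- function(record, ke = 0.0578) {
  tr <- record$troughs
  n <- nrow(tr)
  if (n < 2) stop("patient ", record$patient_id, " has < 2 troughs")
  if (!length(ke) %in% c(1L, n - 1L)) {
    stop("ke must be a scalar or one value per target trough")
  }
  labs <- lab_values_at(record$labs, tr$time_h)
  colnames(labs) <- .analytes
  static_vec <- encode_static(record$static)
  offset <- if (!is.null(record$static$transplant_offset_h)) {
    record$static$transplant_offset_h
  } else 0
  doses_to <- function(t) record$doses[record$doses$time_h <= t, ,
                                       drop = FALSE]
  lag_block <- function(k, ke_j) {
    amt <- remaining_amount(doses_to(tr$time_h[k]), tr$time_h[k], ke_j)
    c(remaining_mg = amt, conc_ng_ml = tr$conc_ng_ml[k],
      emp_alpha = empirical_alpha(tr$conc_ng_ml[k], doses_to(tr$time_h[k]),
                                  tr$time_h[k], ke_j),
      labs[k, ])
  }
  rows <- lapply(2:n, function(j) {
    ke_j <- if (length(ke) == 1) ke else ke[j - 1]
    b1 <- lag_block(j - 1, ke_j)
    b2 <- if (j >= 3) c(lag_block(j - 2, ke_j), has_lag2 = 1) else {
      c(stats::setNames(numeric(length(b1)), names(b1)), has_lag2 = 0)
    }
    names(b1) <- paste0("lag1_", names(b1))
    names(b2) <- c(paste0("lag2_", names(b2)[-length(b2)]), "has_lag2")
    tgt_amt <- remaining_amount(doses_to(tr$time_h[j]), tr$time_h[j], ke_j)
    daily <- sum(record$doses$dose_mg[record$doses$time_h > tr$time_h[j] - 24 &
                                        record$doses$time_h <= tr$time_h[j]])
    as.data.frame(as.list(c(
      b1, b2,
      t_after_transplant_h = offset + tr$time_h[j],
      t_after_first_dose_h = tr$time_h[j],
      dt_prev_trough_h = tr$time_h[j] - tr$time_h[j - 1],
      daily_dose_mg = daily,
      static_vec,
      target_remaining_mg = tgt_amt,
      target_conc = tr$conc_ng_ml[j],
      target_index = j
    )))
  })
  out <- do.call(rbind, rows)
  out$patient_id <- record$patient_id
  out$ke_used <- if (length(ke) == 1) ke else ke[out$target_index - 1]
  out
}

#' Lag-feature rows for a whole cohort
#'
#' @param cohort A `tac_cohort`.
#' @param ke Fixed population ke (default 0.0578 1/h), or a function
#'   `function(record)` returning one ke per target trough (e.g. a wrapper
#'   around [map_ke_per_target()] for the integrated ML-PopPK variant).
#' @return data.frame of stacked rows.
#' @export
cohort_lag_features <- function(cohort, ke = 0.0578) {
  stopifnot(inherits(cohort, "tac_cohort"))
  rows <- do.call(rbind, lapply(cohort, function(r) {
    k <- if (is.function(ke)) ke(r) else ke
    build_lag_features(r, k)
  }))
  rownames(rows) <- NULL
  rows
}
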