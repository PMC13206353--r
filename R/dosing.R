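# Dose recommendation: invert the trough forecast over a 0.5-mg candidate
# grid of q12h maintenance doses, returning every dose whose forecast falls
# in the therapeutic window, a point recommendation nearest the window
# midpoint (ties -> lower dose), and safety flags.

#' Recommend q12h doses for a target trough window
#'
#' For each candidate dose d the realized dose history is extended with q12h
#' administrations of d (starting one interval after the last recorded dose,
#' or at `t_now` if the history is empty) up to the forecast time
#' `t_now + horizon_h`, and the trough there is forecast through the
#' superposition equation at the supplied individual (alpha, ke). Because
#' alpha > 0 the forecast is strictly increasing in d, so the admissible set
#' is a contiguous run of the grid.
#'
#' @param params A [pk_params()] pair, e.g. from [gru_estimate_params()].
#' @param doses Realized dose-event history (may be empty).
#' @param t_now Current time (typically the latest trough), h.
#' @param target Therapeutic window, ng/mL (closed on both ends).
#' @param horizon_h Forecast horizon; default one day (the next scheduled
#'   TDM).
#' @param interval_h Dosing interval, h.
#' @param grid Candidate doses, mg (0.5-mg steps by default).
#' @param prior_dose Last administered dose, mg; candidates exceeding 1.5x
#'   this are flagged `excessive_change`. Taken from the history when
#'   omitted.
#' @return List of class `dose_recommendation`: `admissible_mg`, `point_mg`
#'   (NA when the admissible set is empty), `forecasts` (data.frame dose_mg,
#'   trough_ng_ml, excessive_change), `nearest_mg` (dose with forecast
#'   closest to the window midpoint, as a diagnostic when the set is empty),
#'   `future_times_h`, `target`.
#' @export
recommend <- function(params, doses, t_now, target = c(8, 12),
                      horizon_h = 24, interval_h = 12,
                      grid = seq(0.5, 15, by = 0.5), prior_dose = NULL) {
  stopifnot(inherits(params, "pk_params"), target[1] < target[2],
            horizon_h > 0, all(diff(grid) > 0))
  if (nrow(doses) && any(doses$time_h > t_now)) {
    stop("dose history extends beyond t_now")
  }
  if (is.null(prior_dose) && nrow(doses)) {
    prior_dose <- doses$dose_mg[which.max(doses$time_h)]
  }
  t_fc <- t_now + horizon_h
  t_start <- if (nrow(doses)) max(doses$time_h) + interval_h else t_now
  # the trough is drawn just before an administration: a dose scheduled at
  # the forecast instant has not been given yet
  future <- if (t_start < t_fc - 1e-6) {
    f <- seq(t_start, t_fc, by = interval_h)
    f[f < t_fc - 1e-6]
  } else numeric(0)

  fc <- vapply(grid, function(d) {
    all_doses <- rbind(doses[, c("time_h", "dose_mg")],
                       if (length(future)) {
                         data.frame(time_h = future, dose_mg = d)
                       })
    conc_simplified(all_doses, t_fc, params)
  }, numeric(1))

  excessive <- if (!is.null(prior_dose)) grid > 1.5 * prior_dose
               else rep(FALSE, length(grid))
  ok <- fc >= target[1] & fc <= target[2]
  if (any(ok) && length(future)) {
    stopifnot(all(diff(which(ok)) == 1)) # contiguity under monotone forecast
  }
  admissible <- grid[ok]
  mid <- mean(target)
  point <- if (length(admissible)) {
    # nearest to the window midpoint; ties resolved to the lower dose
    adm_fc <- fc[ok]
    admissible[order(abs(adm_fc - mid), admissible)][1]
  } else NA_real_
  structure(list(
    admissible_mg = admissible,
    point_mg = point,
    forecasts = data.frame(dose_mg = grid, trough_ng_ml = fc,
                           excessive_change = excessive),
    nearest_mg = grid[which.min(abs(fc - mid))],
    future_times_h = future,
    target = target,
    prior_dose = prior_dose
  ), class = "dose_recommendation")
}

#' Classify an administered dose against a recommendation
#'
#' @param actual_dose Administered dose, mg.
#' @param rec A `dose_recommendation`.
#' @return `"within"`, `"below"`, `"above"` (closed bounds of the admissible
#'   set's hull) or `"no_recommendation"` when the admissible set is empty.
#' @export
recommend_range_check <- function(actual_dose, rec) {
  stopifnot(inherits(rec, "dose_recommendation"))
  if (!length(rec$admissible_mg)) return("no_recommendation")
  if (actual_dose < min(rec$admissible_mg)) return("below")
  if (actual_dose > max(rec$admissible_mg)) return("above")
  "within"
}

#' Retrospective dose-recommendation decisions for a cohort
#'
#' For every target trough: estimate (alpha, ke) from the history (any model
#' exposing per-sample parameters), recommend doses for the interval up to
#' the target time, and compare with the dose actually administered in that
#' interval (the first administration after the decision point). Feeds
#' [target_attainment()].
#'
#' @param cohort A `tac_cohort`.
#' @param param_fn `function(sample) -> pk_params` (e.g. a wrapper around
#'   [gru_estimate_params()] or a MAP-estimate adapter).
#' @param target Therapeutic window, ng/mL.
#' @param grid Candidate doses, mg.
#' @return data.frame: patient_id, target_index, observed, actual_dose,
#'   rec_min, rec_max, point_mg, category.
#' @export
recommendation_table <- function(cohort, param_fn, target = c(8, 12),
                                 grid = seq(0.5, 15, by = 0.5)) {
  stopifnot(inherits(cohort, "tac_cohort"))
  ids <- vapply(cohort, `[[`, "", "patient_id")
  rows <- lapply(cohort, function(rec) {
    samples <- build_sequences(rec)
    do.call(rbind, lapply(samples, function(s) {
      t_now <- max(s$features[, "t_h"])
      hist <- rec$doses[rec$doses$time_h <= t_now, , drop = FALSE]
      p <- param_fn(s)
      r <- recommend(p, hist, t_now, target = target,
                     horizon_h = s$target_time - t_now, grid = grid)
      after <- rec$doses$time_h > t_now
      actual <- if (any(after)) {
        rec$doses$dose_mg[after][which.min(rec$doses$time_h[after])]
      } else NA_real_
      data.frame(patient_id = s$patient_id, target_index = s$target_index,
                 observed = s$target_conc,
                 actual_dose = actual,
                 rec_min = if (length(r$admissible_mg)) min(r$admissible_mg)
                           else NA_real_,
                 rec_max = if (length(r$admissible_mg)) max(r$admissible_mg)
                           else NA_real_,
                 point_mg = r$point_mg,
                 category = if (is.na(actual)) "no_dose"
                            else recommend_range_check(actual, r))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
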