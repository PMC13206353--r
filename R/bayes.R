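# Sequential a-posteriori Bayesian (MAP) forecasting baseline. A
# one-compartment first-order-absorption structural model with log-normal
# inter-individual variability on CL/F and V/F and a proportional residual
# error model. Forecasting C_trough,n updates the individual empirical Bayes
# estimates from troughs 1..n-1 only, then evaluates the full superposition
# model at the individual parameters. The module is a protocol-faithful
# baseline, deliberately simpler than richer published two-compartment
# tacrolimus models: its role is the sequential MAP forecasting comparator,
# not a numeric clone of any particular population model.

#' Population prior for the MAP forecaster
#'
#' Defaults give a typical ke of 0.07 1/h, inside the plausible 0.017-0.17
#' band. All parameters are apparent (bioavailability-scaled).
#'
#' @param typical_cl Typical apparent clearance CL/F, L/h.
#' @param typical_v Typical apparent volume V/F, L.
#' @param ka Fixed absorption rate constant, 1/h.
#' @param omega_cl,omega_v Log-scale IIV SDs for CL/F and V/F (< 2).
#' @param prop_sd Proportional residual error SD.
#' @return List of class `pop_prior`.
#' @export
pop_prior <- function(typical_cl = 21, typical_v = 300, ka = 4.5,
                      omega_cl = 0.35, omega_v = 0.25, prop_sd = 0.20) {
  stopifnot(typical_cl > 0, typical_v > 0, ka > 0,
            omega_cl >= 0, omega_cl < 2, omega_v >= 0, omega_v < 2,
            prop_sd > 0)
  ke <- typical_cl / typical_v
  if (ka <= ke) stop("prior implies ka <= ke")
  structure(list(typical_cl = typical_cl, typical_v = typical_v, ka = ka,
                 omega_cl = omega_cl, omega_v = omega_v, prop_sd = prop_sd),
            class = "pop_prior")
}

prior_params <- function(prior, eta) {
  cl <- prior$typical_cl * exp(eta[1])
  v <- prior$typical_v * exp(eta[2])
  full_pk_params(ka = prior$ka, ke = cl / v, F = 1, Vd = v)
}

#' MAP update of individual parameters from observed troughs
#'
#' Maximizes the proportional-error log-likelihood plus the log-normal prior
#' on (CL/F, V/F) over the log-scale deviations eta, by bounded quasi-Newton
#' optimization with three starts. With no observations the population
#' typical values are returned (eta = 0). Non-convergence of all starts
#' falls back to the population typical values with a warning.
#'
#' @param prior A [pop_prior()].
#' @param doses Dose-event table (history).
#' @param troughs data.frame with `time_h`, `conc_ng_ml` (troughs 1..n-1;
#'   may have zero rows).
#' @return List of class `map_estimate`: `eta`, implied `cl_f`, `v_f`, `ke`,
#'   `n_obs`, `converged`.
#' @export
map_update <- function(prior, doses, troughs) {
  stopifnot(inherits(prior, "pop_prior"))
  n_obs <- nrow(troughs)
  as_estimate <- function(eta, converged) {
    p <- prior_params(prior, eta)
    structure(list(eta = eta, cl_f = prior$typical_cl * exp(eta[1]),
                   v_f = p$Vd, ke = p$ke, n_obs = n_obs,
                   converged = converged),
              class = "map_estimate")
  }
  if (n_obs == 0) return(as_estimate(c(0, 0), TRUE))
  if (any(troughs$conc_ng_ml <= 0)) stop("troughs must be positive")

  free <- c(prior$omega_cl > 0, prior$omega_v > 0)
  # each observation sees only the doses administered before it
  dose_sets <- lapply(troughs$time_h, function(t) {
    doses[doses$time_h < t, , drop = FALSE]
  })
  nlp <- function(eta_free) {
    eta <- c(0, 0)
    eta[free] <- eta_free
    p <- tryCatch(prior_params(prior, eta), error = function(e) NULL)
    if (is.null(p)) return(1e10)
    f <- vapply(seq_len(n_obs), function(i) {
      conc_full(dose_sets[[i]], troughs$time_h[i], p)
    }, numeric(1))
    if (any(f <= 1e-9)) return(1e10)
    sum(0.5 * ((troughs$conc_ng_ml - f) / (prior$prop_sd * f))^2 + log(f)) +
      sum(0.5 * (eta[free] / c(prior$omega_cl, prior$omega_v)[free])^2)
  }
  if (!any(free)) return(as_estimate(c(0, 0), TRUE))

  starts <- list(rep(0, sum(free)), rep(0.7, sum(free)), rep(-0.7, sum(free)))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, nlp, method = "L-BFGS-B",
                   lower = rep(-4, sum(free)), upper = rep(4, sum(free))),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    warning("MAP optimization failed; falling back to population typical")
    return(as_estimate(c(0, 0), FALSE))
  }
  eta <- c(0, 0)
  eta[free] <- best$par
  as_estimate(eta, best$convergence == 0)
}

#' Forecast the next trough from a MAP estimate
#'
#' One-compartment first-order-absorption concentration at `t_next`,
#' evaluated through [conc_full()] at the individual parameters.
#'
#' @param est A `map_estimate`.
#' @param prior The [pop_prior()] it was fitted under.
#' @param doses Dose-event table up to `t_next`.
#' @param t_next Forecast time, h.
#' @return Concentration, ng/mL.
#' @export
forecast_next <- function(est, prior, doses, t_next) {
  stopifnot(inherits(est, "map_estimate"), inherits(prior, "pop_prior"))
  conc_full(doses, t_next, prior_params(prior, est$eta))
}

#' Sequential MAP forecasts for every target trough of a cohort
#'
#' For each patient and each trough after the first, the individual estimate
#' is updated from the strictly earlier troughs and the next trough is
#' forecast — the sequential a-posteriori protocol.
#'
#' @param cohort A `tac_cohort`.
#' @param prior A [pop_prior()].
#' @return data.frame: patient_id, target_index, observed, predicted, cl_f,
#'   v_f, ke.
#' @export
bayes_forecast_cohort <- function(cohort, prior = pop_prior()) {
  stopifnot(inherits(cohort, "tac_cohort"))
  out <- lapply(cohort, function(rec) {
    tr <- rec$troughs
    rows <- lapply(2:nrow(tr), function(j) {
      est <- map_update(prior,
                        rec$doses[rec$doses$time_h < tr$time_h[j], ,
                                  drop = FALSE],
                        tr[seq_len(j - 1), , drop = FALSE])
      pred <- forecast_next(
        est, prior,
        rec$doses[rec$doses$time_h <= tr$time_h[j], , drop = FALSE],
        tr$time_h[j])
      data.frame(patient_id = rec$patient_id, target_index = j,
                 observed = tr$conc_ng_ml[j], predicted = pred,
                 cl_f = est$cl_f, v_f = est$v_f, ke = est$ke)
    })
    do.call(rbind, rows)
  })
  do.call(rbind, out)
}

#' Per-target individual ke estimates from prior troughs
#'
#' Supplies the `per_patient` ke mode of the boosted model (the integrated
#' ML-PopPK variant): for each target trough the ke implied by the MAP
#' estimate from the strictly earlier troughs.
#'
#' @param record One patient record.
#' @param prior A [pop_prior()].
#' @return Numeric vector, one ke per target trough (indices 2..n).
#' @export
map_ke_per_target <- function(record, prior = pop_prior()) {
  tr <- record$troughs
  vapply(2:nrow(tr), function(j) {
    est <- map_update(prior,
                      record$doses[record$doses$time_h < tr$time_h[j], ,
                                   drop = FALSE],
                      tr[seq_len(j - 1), , drop = FALSE])
    est$ke
  }, numeric(1))
}
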