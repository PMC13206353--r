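# Deterministic pharmacokinetic engine: multiple-dose superposition with
# first-order absorption/elimination, its trough-time simplification,
# remaining drug amount, and the empirical composite exposure parameter.
#
# Unit conventions (used everywhere in the package):
#   doses mg, concentrations ng/mL, times hours since first tacrolimus dose.
#   The full model computes mg/L and reports ng/mL (= ug/L), i.e. a x1000
#   mg -> ug factor; in the simplified model this factor is absorbed into
#   alpha, which therefore carries (ng/mL) per mg of remaining drug.

#' Construct a validated dose-event table
#'
#' @param time_h Numeric vector of administration times, hours since the
#'   first dose (finite, non-negative).
#' @param dose_mg Numeric vector of administered amounts in mg (> 0).
#' @return A `data.frame` with columns `time_h`, `dose_mg`, sorted by time.
#'   Within a patient dose times must be strictly increasing after sorting.
#' @export
dose_events <- function(time_h = numeric(), dose_mg = numeric()) {
  time_h <- as.numeric(time_h)
  dose_mg <- as.numeric(dose_mg)
  if (length(time_h) != length(dose_mg)) {
    stop("time_h and dose_mg must have equal length")
  }
  if (length(time_h)) {
    if (any(!is.finite(time_h)) || any(time_h < 0)) {
      stop("dose times must be finite and non-negative")
    }
    if (any(!is.finite(dose_mg)) || any(dose_mg <= 0)) {
      stop("dose amounts must be finite and > 0")
    }
    o <- order(time_h)
    time_h <- time_h[o]
    dose_mg <- dose_mg[o]
    if (anyDuplicated(time_h)) {
      stop("duplicated dose times within a patient")
    }
  }
  data.frame(time_h = time_h, dose_mg = dose_mg)
}

#' One-compartment PK parameter set with first-order absorption
#'
#' @param ka Absorption rate constant, 1/h. Must exceed `ke`.
#' @param ke Elimination rate constant, 1/h (> 0).
#' @param F Bioavailability fraction in (0, 1].
#' @param Vd Volume of distribution, L (> 0).
#' @return A named list of class `full_pk_params`.
#' @export
full_pk_params <- function(ka, ke, F, Vd) {
  stopifnot(is.finite(ka), is.finite(ke), is.finite(F), is.finite(Vd))
  if (ke <= 0) stop("ke must be > 0")
  if (ka <= ke) stop("ka must exceed ke (first-order absorption model)")
  if (F <= 0 || F > 1) stop("F must lie in (0, 1]")
  if (Vd <= 0) stop("Vd must be > 0")
  structure(list(ka = ka, ke = ke, F = F, Vd = Vd),
            class = "full_pk_params")
}

#' Composite (alpha, ke) parameter pair used by the trough simplification
#'
#' `alpha` maps remaining drug amount (mg) to concentration (ng/mL); the
#' mg -> ug unit factor is absorbed into alpha. When produced by the
#' constrained recurrent-model head, `ke` lies in \[0.017, 0.17\] 1/h.
#'
#' @param alpha Composite exposure parameter, (ng/mL)/mg (> 0).
#' @param ke Elimination rate constant, 1/h (>= 0; 0 permitted for tests).
#' @return A named list of class `pk_params`.
#' @export
pk_params <- function(alpha, ke) {
  stopifnot(is.finite(alpha), is.finite(ke))
  if (alpha <= 0) stop("alpha must be > 0")
  if (ke < 0) stop("ke must be >= 0")
  structure(list(alpha = alpha, ke = ke), class = "pk_params")
}

#' Full composite exposure parameter in reporting units
#'
#' alpha = 1000 * F * ka / (Vd * (ka - ke)), in (ng/mL) per mg of remaining
#' drug; the factor 1000 converts mg/L to ng/mL.
#'
#' @param p A `full_pk_params` object.
#' @return alpha, (ng/mL)/mg.
#' @export
composite_alpha <- function(p) {
  1000 * p$F * p$ka / (p$Vd * (p$ka - p$ke))
}

#' Multiple-dose concentration under first-order absorption (full model)
#'
#' Superposition over all administered doses:
#' C(t) = sum_i (F ka / (Vd (ka - ke))) D_i (exp(-ke (t - t_i)) -
#' exp(-ka (t - t_i))), evaluated in mg/L and reported as ng/mL.
#'
#' @param doses Dose-event table from [dose_events()]; all times must be <= t.
#' @param t Time(s) of evaluation, h since first dose (vectorized).
#' @param p A `full_pk_params` object.
#' @return Concentration(s) in ng/mL.
#' @export
conc_full <- function(doses, t, p) {
  stopifnot(inherits(p, "full_pk_params"))
  vapply(t, function(tt) {
    if (!nrow(doses)) return(0)
    if (any(doses$time_h > tt)) {
      stop("dose administered after evaluation time ", tt)
    }
    tau <- tt - doses$time_h
    scale <- p$F * p$ka / (p$Vd * (p$ka - p$ke))
    mg_per_l <- scale * sum(doses$dose_mg * (exp(-p$ke * tau) - exp(-p$ka * tau)))
    1000 * mg_per_l
  }, numeric(1))
}

#' Remaining drug amount at time t
#'
#' sum_i D_i exp(-ke (t - t_i)), mg. With ke = 0 this is the cumulative
#' administered dose (useful in tests).
#'
#' @param doses Dose-event table; all times must be <= t.
#' @param t Evaluation time(s), h (vectorized).
#' @param ke Elimination rate constant, 1/h (>= 0).
#' @return Remaining amount(s), mg.
#' @export
remaining_amount <- function(doses, t, ke) {
  stopifnot(is.finite(ke), ke >= 0)
  vapply(t, function(tt) {
    if (!nrow(doses)) return(0)
    if (any(doses$time_h > tt)) {
      stop("dose administered after evaluation time ", tt)
    }
    sum(doses$dose_mg * exp(-ke * (tt - doses$time_h)))
  }, numeric(1))
}

# Derivative of remaining_amount with respect to ke; consumed by the
# recurrent model's backward pass.
remaining_amount_dke <- function(doses, t, ke) {
  vapply(t, function(tt) {
    if (!nrow(doses)) return(0)
    tau <- tt - doses$time_h
    -sum(doses$dose_mg * tau * exp(-ke * tau))
  }, numeric(1))
}

#' Trough concentration under the simplified (absorption-complete) model
#'
#' C(t) = alpha * sum_i D_i exp(-ke (t - t_i)). Exactly linear in any
#' uniform scaling of the dose amounts and additive over dose lists.
#'
#' @param doses Dose-event table; all times must be <= t.
#' @param t Evaluation time(s), h.
#' @param p A `pk_params` object (alpha, ke).
#' @return Concentration(s) in ng/mL.
#' @export
conc_simplified <- function(doses, t, p) {
  stopifnot(inherits(p, "pk_params"))
  p$alpha * remaining_amount(doses, t, p$ke)
}

#' Empirical composite exposure parameter from one trough
#'
#' The ratio of an observed trough concentration to the remaining drug
#' amount at the observation time. Inverts [conc_simplified()] exactly when
#' the same ke is used.
#'
#' @param conc Observed trough, ng/mL (> 0).
#' @param doses Dose-event table up to the trough time.
#' @param t Trough time, h.
#' @param ke Elimination rate constant used to compute the remaining amount.
#' @return alpha in (ng/mL)/mg.
#' @export
empirical_alpha <- function(conc, doses, t, ke) {
  stopifnot(is.finite(conc), conc > 0)
  amt <- remaining_amount(doses, t, ke)
  if (amt <= 1e-12) stop("remaining drug amount is ~0; empirical alpha undefined")
  conc / amt
}
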