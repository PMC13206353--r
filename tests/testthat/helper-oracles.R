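# Independent oracle implementations used to cross-check package code.
# Deliberately written as plain loops so they share no code path with the
# package.

# One-compartment multiple-dose concentration, ng/mL (loop form)
oracle_conc <- function(dose_times, dose_mg, t, ka, ke, F, Vd) {
  total <- 0
  for (i in seq_along(dose_times)) {
    tau <- t - dose_times[i]
    total <- total + dose_mg[i] * (exp(-ke * tau) - exp(-ka * tau))
  }
  1000 * F * ka / (Vd * (ka - ke)) * total
}

oracle_remaining <- function(dose_times, dose_mg, t, ke) {
  total <- 0
  for (i in seq_along(dose_times)) {
    total <- total + dose_mg[i] * exp(-ke * (t - dose_times[i]))
  }
  total
}

# Loop-based recomputation of the metric suite
oracle_metrics <- function(obs, pred) {
  n <- length(obs)
  se <- ae <- rel <- rel2 <- numeric(n)
  for (i in seq_len(n)) {
    se[i] <- (pred[i] - obs[i])^2
    ae[i] <- abs(pred[i] - obs[i])
    rel[i] <- (pred[i] - obs[i]) / obs[i]
    rel2[i] <- rel[i]^2
  }
  ybar <- sum(obs) / n
  sst <- sum((obs - ybar)^2)
  list(mse = sum(se) / n, mae = sum(ae) / n,
       r2 = 1 - sum(se) / sst,
       mpe = 100 * sum(rel) / n,
       rmsrpe = 100 * sqrt(sum(rel2) / n),
       p10 = 100 * sum(abs(rel) <= 0.10) / n,
       p20 = 100 * sum(abs(rel) <= 0.20) / n,
       p30 = 100 * sum(abs(rel) <= 0.30) / n)
}

# A hand-built three-patient record set used across data-io tests
tiny_record <- function(pid = "X1", trough_times = c(23.5, 47.5),
                        conc = c(9, 11), weight = 80) {
  dose_times <- seq(0, 60, by = 12)
  labs <- do.call(rbind, lapply(
    c("haematocrit", "albumin", "alt", "ast", "creatinine"),
    function(a) data.frame(analyte = a, time_h = c(0, 48),
                           value = c(30, 34))))
  list(patient_id = pid,
       doses = dose_events(dose_times, rep(6, length(dose_times))),
       troughs = data.frame(time_h = trough_times, conc_ng_ml = conc),
       labs = labs,
       static = data.frame(patient_id = pid, age = 50, sex = "M",
                           race = "Caucasian", height_cm = 175,
                           weight_kg = weight, bmi = 26.1, bsa = 1.97,
                           smoking = 0L, alcohol = 0L,
                           cyp3a_inhibitor = 0L, cyp3a_inducer = 0L))
}

tiny_cohort <- function(n = 3) {
  structure(lapply(seq_len(n), function(i) {
    tiny_record(pid = sprintf("X%d", i),
                trough_times = c(23.5, 47.5) + i,
                conc = c(9, 11) + 0.5 * i)
  }), class = "tac_cohort")
}
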