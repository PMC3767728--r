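# Degenerate fixtures: all dispersion and event probabilities switched off,
# single population cell, so episode traces are hand-computable.

degenerate_population <- function(procedure = "hip", sex = "female",
                                  age = 70, weight = 80, base_los = 10,
                                  revision_probability = 0,
                                  asa_ge3_probability = 0) {
  pop <- data.frame(
    row_id = "cell1", procedure = procedure, sex = sex,
    age_lo = age, age_hi = age, frequency = 1,
    weight_mean = weight, weight_sd = 0,
    revision_probability = revision_probability,
    asa_ge3_probability = asa_ge3_probability,
    base_los = base_los, stringsAsFactors = FALSE)
  class(pop) <- c("bloodsim_population", "data.frame")
  pop
}

degenerate_config <- function(baseline_hb = 12, n_patients = 1L, seed = 1L,
                              ...) {
  cfg <- default_config(n_patients = n_patients, seed = seed)
  cfg$population <- degenerate_population(...)
  cl <- cfg$clinical
  cl$blood_loss_sd <- 0
  cl$pad_hb_decrement_sd <- 0
  cl$epo_regimen$per_injection_increment_sd <- 0
  cl$p_pneumonia_base <- 0
  cl$p_pneumonia_transfused <- 0
  cl$p_infection_base <- 0
  cl$p_infection_transfused <- 0
  cl$rheumatoid_risk_hip <- 0
  cl$rheumatoid_risk_knee <- 0
  cl$cardiac_history_prob <- 0
  cfg$clinical <- cl
  # enormous shape concentrates the Weibull at its scale
  cfg$hb_weibull_female <- list(shape = 1e7, scale = baseline_hb, location = 0)
  cfg$hb_weibull_male <- list(shape = 1e7, scale = baseline_hb, location = 0)
  cfg
}

degenerate_patient <- function(baseline_hb = 12, procedure = "hip",
                               age = 70, rheumatoid = FALSE,
                               cardiac_history = FALSE, asa_ge3 = FALSE,
                               revision = FALSE, blood_loss_hb = 3.3,
                               base_los = 10) {
  structure(list(
    patient_id = 1L, procedure = procedure, revision = revision, age = age,
    age_band = c(age, age), sex = "female", weight = 80,
    ebv = 80 * 65, baseline_hb = baseline_hb, asa_ge3 = asa_ge3,
    rheumatoid = rheumatoid, cardiac_history = cardiac_history,
    blood_loss_hb = blood_loss_hb, base_los = base_los
  ), class = "bloodsim_patient")
}
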