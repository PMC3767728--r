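ARM_NAMES <- c("ABT", "PAD", "EPO")

## one arm's surgical episode; caller has positioned the RNG stream and
## already applied the arm's preoperative adjustment
simulate_arm_episode <- function(profile, state, config) {
  cl <- config$clinical
  postop <- postoperative_hb(state$preop_hb_adjusted, profile$blood_loss_hb)
  trig <- effective_trigger(cl$transfusion_trigger, profile$cardiac_history,
                            cl$cardiac_trigger_shift)
  need <- units_required(postop, trig, cl$hb_per_unit,
                         cl$transfuse_at_equality)
  units <- transfuse(need, state$autologous_units_available)
  transfused <- need > 0L
  infection <- sample_infection(transfused, cl)
  pneumonia <- sample_pneumonia(transfused, cl)
  los <- length_of_stay(profile$base_los, transfused, infection, cl)
  cost <- cost_components(config$costs, state$epo_doses_given,
                          units$allogeneic, state$pad_applicable, los,
                          pneumonia)
  list(
    preop_hb_adjusted = state$preop_hb_adjusted,
    hb_change = state$hb_change,
    autologous_units_available = state$autologous_units_available,
    epo_doses_given = state$epo_doses_given,
    epo_doses_effective = state$epo_doses_effective,
    pad_applicable = state$pad_applicable,
    postop_hb = postop,
    effective_trigger = trig,
    units_needed = need,
    autologous_units = units$autologous,
    allogeneic_units = units$allogeneic,
    transfused = transfused,
    infection = infection,
    pneumonia = pneumonia,
    final_hb = postop + need * cl$hb_per_unit,
    los = los,
    epo_cost = cost$epo_cost,
    transfusion_allogeneic_cost = cost$transfusion_allogeneic_cost,
    pad_collection_cost = cost$pad_collection_cost,
    los_cost = cost$los_cost,
    pneumonia_cost = cost$pneumonia_cost,
    total_cost = cost$total_cost
  )
}

#' Run one patient through all three strategy arms
#'
#' The patient is cloned across the allogeneic-only, autologous-donation and
#' epoetin arms with identical characteristics; each arm's preoperative
#' adjustment and episode events (transfusion demand, infection, pneumonia,
#' length of stay, costs) are drawn from an independent random sub-stream
#' derived deterministically from \code{(config$seed, patient_id, arm)}.
#'
#' @param profile a \code{bloodsim_patient}.
#' @param config a validated \code{bloodsim_config}.
#' @return A list of class \code{bloodsim_record} with the shared
#'   \code{$profile} and \code{$outcomes}, a list with one episode record
#'   per arm.
#' @export
run_patient <- function(profile, config) {
  outcomes <- vector("list", length(ARM_NAMES))
  names(outcomes) <- ARM_NAMES
  for (arm in ARM_NAMES) {
    set.seed(derive_stream_seed(config$seed, profile$patient_id,
                                STREAM_ARM[[arm]]))
    state <- switch(arm,
      ABT = apply_abt(profile),
      PAD = apply_pad(profile, config$clinical),
      EPO = apply_epo(profile, config$clinical))
    outcomes[[arm]] <- simulate_arm_episode(profile, state, config)
  }
  structure(list(profile = profile, outcomes = outcomes),
            class = "bloodsim_record")
}

#' Run the full patient-level simulation
#'
#' Creates \code{n_patients} patients from the configured population table
#' and clones each across the three blood-management arms. All randomness is
#' keyed to \code{config$seed}: characteristics on a per-patient stream
#' (common random numbers across arms and scenarios), episode events on
#' per-(patient, arm) streams.
#'
#' @param config a validated \code{bloodsim_config}.
#' @param n_patients optional override of \code{config$n_patients}.
#' @return An object of class \code{bloodsim_run} with \code{$patients}
#'   (one row per patient), \code{$outcomes} (one row per patient and arm)
#'   and \code{$config}. Summarize with [summary()] /
#'   [stratify_and_summarize()].
#' @export
#' @examples
#' run <- run_simulation(default_config(n_patients = 50, seed = 1))
#' summary(run)
run_simulation <- function(config, n_patients = NULL) {
  validate_config(config)
  if (!is.null(n_patients)) config$n_patients <- as.integer(n_patients)
  n <- config$n_patients
  if (is.null(config$population)) {
    config$population <- generate_fixture_population()
  }

  prof_cols <- c("patient_id", "age", "weight", "ebv", "baseline_hb",
                 "blood_loss_hb", "base_los")
  prof_num <- matrix(0, n, length(prof_cols),
                     dimnames = list(NULL, prof_cols))
  procedure <- character(n); sex <- character(n)
  flags <- matrix(FALSE, n, 4,
                  dimnames = list(NULL, c("revision", "asa_ge3", "rheumatoid",
                                          "cardiac_history")))

  out_cols <- c("patient_id", "preop_hb_adjusted", "hb_change",
                "autologous_units_available", "epo_doses_given",
                "epo_doses_effective", "pad_applicable", "postop_hb",
                "effective_trigger", "units_needed", "autologous_units",
                "allogeneic_units", "transfused", "infection", "pneumonia",
                "final_hb", "los", "epo_cost", "transfusion_allogeneic_cost",
                "pad_collection_cost", "los_cost", "pneumonia_cost",
                "total_cost")
  out_num <- matrix(0, n * 3L, length(out_cols),
                    dimnames = list(NULL, out_cols))
  arm_col <- rep(ARM_NAMES, times = n)

  for (i in seq_len(n)) {
    p <- create_patient(i, config)
    prof_num[i, ] <- c(p$patient_id, p$age, p$weight, p$ebv, p$baseline_hb,
                       p$blood_loss_hb, p$base_los)
    procedure[i] <- p$procedure
    sex[i] <- p$sex
    flags[i, ] <- c(p$revision, p$asa_ge3, p$rheumatoid, p$cardiac_history)
    rec <- run_patient(p, config)
    for (a in 1:3) {
      o <- rec$outcomes[[ARM_NAMES[a]]]
      out_num[(i - 1L) * 3L + a, ] <- c(p$patient_id, o$preop_hb_adjusted,
        o$hb_change, o$autologous_units_available, o$epo_doses_given,
        o$epo_doses_effective, o$pad_applicable, o$postop_hb,
        o$effective_trigger, o$units_needed, o$autologous_units,
        o$allogeneic_units, o$transfused, o$infection, o$pneumonia,
        o$final_hb, o$los, o$epo_cost, o$transfusion_allogeneic_cost,
        o$pad_collection_cost, o$los_cost, o$pneumonia_cost, o$total_cost)
    }
  }

  patients <- data.frame(prof_num, procedure = procedure, sex = sex, flags,
                         stringsAsFactors = FALSE)
  outcomes <- data.frame(out_num, arm = arm_col, stringsAsFactors = FALSE)
  for (f in c("pad_applicable", "transfused", "infection", "pneumonia")) {
    outcomes[[f]] <- as.logical(outcomes[[f]])
  }
  structure(list(patients = patients, outcomes = outcomes, config = config),
            class = "bloodsim_run")
}

#' @export
print.bloodsim_run <- function(x, ...) {
  cat(sprintf("<bloodsim_run> '%s': %d patients x 3 arms (seed %d)\n",
              x$config$name, nrow(x$patients), x$config$seed))
  for (arm in ARM_NAMES) {
    o <- x$outcomes[x$outcomes$arm == arm, ]
    cat(sprintf("  %s: transfused %5.1f%%, mean LOS %5.2f d, mean total EUR %8.2f\n",
                arm, 100 * mean(o$transfused), mean(o$los),
                mean(o$total_cost)))
  }
  invisible(x)
}

#' @export
summary.bloodsim_run <- function(object, ...) {
  stratify_and_summarize(object, ...)
}
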