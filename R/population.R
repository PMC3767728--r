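#' Synthetic procedure-mix population table
#'
#' Builds a schema-valid population table emulating the structure of the
#' German elective hip/knee arthroplasty case mix: procedure strata crossed
#' with age bands and sex, each cell carrying a sampling frequency, a
#' weight distribution, procedure-level revision and ASA >= III risks, and a
#' base length of stay. The table is synthetic — strata are abstract, not
#' real DRG codes — and its defaults target a hip share of about 57%, a
#' female share of about 65% and a mean age near 70 years.
#'
#' @param hip_share probability mass on hip procedures.
#' @param female_share probability mass on female patients.
#' @param age_bands two-column matrix (or list of length-2 vectors) of
#'   inclusive integer age-band bounds.
#' @param age_weights probability weights over \code{age_bands}
#'   (normalized internally).
#' @param revision_probability,asa_ge3_probability per-stratum risks.
#' @param base_los_hip,base_los_knee base length of stay in days.
#' @param frequency_jitter_sd if positive, cell frequencies are perturbed by
#'   multiplicative lognormal noise with this log-scale SD (then
#'   renormalized), giving an irregular but reproducible mix under the
#'   ambient RNG state.
#' @return A \code{data.frame} of class \code{bloodsim_population} with one
#'   row per (stratum, age band, sex) cell; frequencies sum to 1.
#' @export
#' @examples
#' pop <- generate_fixture_population()
#' sum(pop$frequency)
generate_fixture_population <- function(hip_share = 0.575,
                                        female_share = 0.65,
                                        age_bands = rbind(c(45, 54), c(55, 64),
                                                          c(65, 74), c(75, 84)),
                                        age_weights = c(0.05, 0.18, 0.42, 0.35),
                                        revision_probability = 0.104,
                                        asa_ge3_probability = 0.40,
                                        base_los_hip = 13,
                                        base_los_knee = 12,
                                        frequency_jitter_sd = 0) {
  if (is.list(age_bands)) age_bands <- do.call(rbind, age_bands)
  stopifnot(ncol(age_bands) == 2, nrow(age_bands) == length(age_weights),
            all(age_bands[, 2] >= age_bands[, 1]),
            hip_share >= 0, hip_share <= 1,
            female_share >= 0, female_share <= 1)
  age_weights <- age_weights / sum(age_weights)

  grid <- expand.grid(band = seq_len(nrow(age_bands)),
                      sex = c("female", "male"),
                      procedure = c("hip", "knee"),
                      stringsAsFactors = FALSE)
  freq <- age_weights[grid$band] *
    ifelse(grid$sex == "female", female_share, 1 - female_share) *
    ifelse(grid$procedure == "hip", hip_share, 1 - hip_share)
  if (frequency_jitter_sd > 0) {
    freq <- freq * stats::rlnorm(length(freq), 0, frequency_jitter_sd)
  }
  freq <- freq / sum(freq)

  ## body weight by sex; mild decline with age band
  mid <- rowMeans(age_bands)[grid$band]
  w_mean <- ifelse(grid$sex == "female", 74, 85) - 0.15 * (mid - 65)
  pop <- data.frame(
    row_id = sprintf("%s_%s_%d_%d", grid$procedure, grid$sex,
                     age_bands[grid$band, 1], age_bands[grid$band, 2]),
    procedure = grid$procedure,
    sex = grid$sex,
    age_lo = age_bands[grid$band, 1],
    age_hi = age_bands[grid$band, 2],
    frequency = freq,
    weight_mean = w_mean,
    weight_sd = 13,
    revision_probability = revision_probability,
    asa_ge3_probability = asa_ge3_probability,
    base_los = ifelse(grid$procedure == "hip", base_los_hip, base_los_knee),
    stringsAsFactors = FALSE
  )
  class(pop) <- c("bloodsim_population", "data.frame")
  validate_population(pop)
  pop
}

POPULATION_COLUMNS <- c("row_id", "procedure", "sex", "age_lo", "age_hi",
                        "frequency", "weight_mean", "weight_sd",
                        "revision_probability", "asa_ge3_probability",
                        "base_los")

#' Validate a population table
#'
#' @param pop a population \code{data.frame} (see
#'   [generate_fixture_population()] for the schema).
#' @return \code{pop}, invisibly, or an error naming the violated invariant.
#' @export
validate_population <- function(pop) {
  if (!is.data.frame(pop) || nrow(pop) == 0)
    stop("population table must be a non-empty data.frame", call. = FALSE)
  missing_cols <- setdiff(POPULATION_COLUMNS, names(pop))
  if (length(missing_cols))
    stop("population table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!all(pop$procedure %in% c("hip", "knee")))
    stop("population procedure must be 'hip' or 'knee'", call. = FALSE)
  if (!all(pop$sex %in% c("female", "male")))
    stop("population sex must be 'female' or 'male'", call. = FALSE)
  if (any(pop$frequency < 0) || abs(sum(pop$frequency) - 1) > 1e-8)
    stop("population frequencies must be >= 0 and sum to 1", call. = FALSE)
  if (any(pop$age_hi < pop$age_lo))
    stop("population age bands must have age_hi >= age_lo", call. = FALSE)
  if (any(pop$base_los <= 0))
    stop("population base_los must be > 0", call. = FALSE)
  for (f in c("revision_probability", "asa_ge3_probability")) {
    if (any(pop[[f]] < 0 | pop[[f]] > 1))
      stop("population ", f, " must be in [0, 1]", call. = FALSE)
  }
  if (any(pop$weight_sd < 0))
    stop("population weight_sd must be >= 0", call. = FALSE)
  invisible(pop)
}

#' Read / write a population table as CSV
#'
#' @param path CSV file with the documented population header.
#' @return \code{read_population}: a validated population table.
#' @export
read_population <- function(path) {
  pop <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(pop) <- c("bloodsim_population", "data.frame")
  validate_population(pop)
  pop
}

#' @rdname read_population
#' @param pop a population table.
#' @export
write_population <- function(pop, path) {
  validate_population(pop)
  utils::write.csv(as.data.frame(pop)[, POPULATION_COLUMNS], path,
                   row.names = FALSE)
  invisible(path)
}

#' Draw one procedure/demographic cell from the population table
#'
#' Samples a (stratum, age band, sex) cell with probability equal to its
#' frequency, using the ambient RNG stream.
#'
#' @param pop a validated population table.
#' @return The selected row as a one-row \code{data.frame}.
#' @export
sample_procedure_cell <- function(pop) {
  if (is.null(pop) || nrow(pop) == 0)
    stop("population table is empty", call. = FALSE)
  idx <- sample.int(nrow(pop), 1L, prob = pop$frequency)
  pop[idx, , drop = FALSE]
}

#' Draw a specific age within an age band
#'
#' Ages are integer and uniform over the inclusive band.
#'
#' @param age_lo,age_hi inclusive integer bounds.
#' @return An integer age.
#' @export
sample_age_within_band <- function(age_lo, age_hi) {
  if (age_hi < age_lo) stop("inverted age band", call. = FALSE)
  ages <- seq.int(age_lo, age_hi)
  if (length(ages) == 1L) return(ages)
  ages[sample.int(length(ages), 1L)]
}

#' Draw a body weight
#'
#' Normal draw for the cell's (age band, sex) stratum, clamped below at a
#' physiological floor.
#'
#' @param weight_mean,weight_sd normal parameters in kg.
#' @param floor lower clamp in kg.
#' @return Weight in kg.
#' @export
sample_weight <- function(weight_mean, weight_sd, floor = 35) {
  max(floor, stats::rnorm(1L, weight_mean, weight_sd))
}

#' Estimated blood volume
#'
#' EBV in ml as body weight times a per-kilogram constant (65 ml/kg by
#' default).
#'
#' @param weight body weight in kg; must be positive.
#' @param ebv_per_kg ml of blood per kg.
#' @return EBV in ml.
#' @export
#' @examples
#' estimated_blood_volume(70) # 4550
estimated_blood_volume <- function(weight, ebv_per_kg = 65) {
  if (any(weight <= 0)) stop("weight must be > 0", call. = FALSE)
  weight * ebv_per_kg
}

#' Draw a baseline hemoglobin level
#'
#' Sex-specific three-parameter Weibull draw (location + Weibull(shape,
#' scale)), clamped to the physiological range [6, 18] g/dl.
#'
#' @param sex \code{"female"} or \code{"male"}.
#' @param config a \code{bloodsim_config} carrying \code{hb_weibull_female}
#'   and \code{hb_weibull_male}.
#' @param n number of draws.
#' @return Hb in g/dl.
#' @export
sample_baseline_hb <- function(sex, config, n = 1L) {
  par <- if (identical(sex, "female")) config$hb_weibull_female
         else config$hb_weibull_male
  if (!is.numeric(par$shape) || par$shape <= 0 ||
      !is.numeric(par$scale) || par$scale <= 0)
    stop("invalid Weibull parameters for baseline Hb", call. = FALSE)
  loc <- if (is.null(par$location)) 0 else par$location
  pmin(18, pmax(6, loc + stats::rweibull(n, par$shape, par$scale)))
}

#' Draw comorbidity and revision flags
#'
#' Independent Bernoulli draws for ASA >= III, rheumatoid arthritis (hip- or
#' knee-specific risk), cardiac history, and revision surgery.
#'
#' @param cell one population-table row.
#' @param clinical the \code{clinical} block of a \code{bloodsim_config}.
#' @return Named logical vector \code{asa_ge3}, \code{rheumatoid},
#'   \code{cardiac_history}, \code{revision}.
#' @export
assign_comorbidities <- function(cell, clinical) {
  ra_risk <- if (cell$procedure == "hip") clinical$rheumatoid_risk_hip
             else clinical$rheumatoid_risk_knee
  p <- c(asa_ge3 = cell$asa_ge3_probability,
         rheumatoid = ra_risk,
         cardiac_history = clinical$cardiac_history_prob,
         revision = cell$revision_probability)
  stats::runif(4L) < p
}

#' Draw surgical blood loss in hemoglobin terms
#'
#' Base loss is a procedure-specific normal draw (truncated at 0), then
#' inflated multiplicatively for ASA >= III, old age and revision surgery.
#'
#' @param procedure \code{"hip"} or \code{"knee"}.
#' @param age,asa_ge3,revision patient characteristics driving the
#'   multipliers.
#' @param clinical the \code{clinical} block of a \code{bloodsim_config}.
#' @return Blood loss as a positive Hb magnitude in g/dl.
#' @export
sample_blood_loss <- function(procedure, age, asa_ge3, revision, clinical) {
  base_mean <- if (procedure == "hip") clinical$blood_loss_mean_hip
               else clinical$blood_loss_mean_knee
  loss <- max(0, stats::rnorm(1L, base_mean, clinical$blood_loss_sd))
  if (asa_ge3) loss <- loss * clinical$asa_loss_factor
  if (age >= clinical$old_age_threshold) loss <- loss * clinical$age_loss_factor
  if (revision) loss <- loss * clinical$revision_loss_factor
  loss
}

#' Create one simulated patient
#'
#' Runs the full patient-creation sequence — cell indexing, age within band,
#' weight, estimated blood volume, baseline hemoglobin, comorbidity flags,
#' and surgical blood loss — on a random stream derived deterministically
#' from \code{(config$seed, id)}, so the same (seed, id) pair always yields
#' the same patient regardless of how many others are created.
#'
#' @param id positive integer patient identifier.
#' @param config a validated \code{bloodsim_config}; if
#'   \code{config$population} is \code{NULL} the default synthetic table is
#'   used.
#' @return A list of class \code{bloodsim_patient} with the fixed patient
#'   characteristics.
#' @export
create_patient <- function(id, config) {
  pop <- config$population
  if (is.null(pop)) pop <- generate_fixture_population()
  cl <- config$clinical

  set.seed(derive_stream_seed(config$seed, id, STREAM_PROFILE))
  cell <- sample_procedure_cell(pop)
  age <- sample_age_within_band(cell$age_lo, cell$age_hi)
  weight <- sample_weight(cell$weight_mean, cell$weight_sd, cl$weight_floor)
  hb <- sample_baseline_hb(cell$sex, config)
  flags <- assign_comorbidities(cell, cl)
  loss <- sample_blood_loss(cell$procedure, age, flags[["asa_ge3"]],
                            flags[["revision"]], cl)

  structure(list(
    patient_id = as.integer(id),
    procedure = cell$procedure,
    revision = flags[["revision"]],
    age = age,
    age_band = c(cell$age_lo, cell$age_hi),
    sex = cell$sex,
    weight = weight,
    ebv = estimated_blood_volume(weight, cl$ebv_per_kg),
    baseline_hb = hb,
    asa_ge3 = flags[["asa_ge3"]],
    rheumatoid = flags[["rheumatoid"]],
    cardiac_history = flags[["cardiac_history"]],
    blood_loss_hb = loss,
    base_los = cell$base_los
  ), class = "bloodsim_patient")
}
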