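#' Base-case model configuration
#'
#' Returns the full base-case configuration of the simulation model: unit
#' costs, clinical constants, the epoetin dosing regimen, the baseline
#' hemoglobin distributions and run settings. Every scenario in the
#' sensitivity grid is expressed as a set of overrides on this object.
#'
#' @details
#' The cost block reflects the hospital perspective of a German arthroplasty
#' admission: EUR 320 per allogeneic red-cell unit, EUR 500 for collection and
#' storage of the two autologous units, EUR 200 per 40,000 IU epoetin dose,
#' EUR 300 per hospital day and EUR 5,000 per treated pneumonia episode.
#'
#' Clinical constants: transfusion trigger 8.5 g/dl Hb (shifted +1 g/dl for
#' patients with a cardiac history), surgical blood loss of 3.3 (hip) and
#' 3.5 (knee) g/dl Hb on average, inflated multiplicatively by 5% for
#' ASA >= III, 5% for age >= 75 and 25% for revision surgery. Length of stay
#' is inflated by 20% after transfusion, 60% after infection and 90% after
#' both. Pneumonia risk is 0.8% untransfused and doubled (1.6%) after any
#' transfusion.
#'
#' @param n_patients number of simulated patients for a full run.
#' @param seed integer master seed; all patient- and arm-level random streams
#'   are derived deterministically from it.
#' @return A nested list of class \code{bloodsim_config}.
#' @seealso [load_config()], [build_scenarios()], [run_simulation()]
#' @export
#' @examples
#' cfg <- default_config(n_patients = 100, seed = 1)
#' cfg$clinical$transfusion_trigger
default_config <- function(n_patients = 50000L, seed = 1L) {
  cfg <- list(
    schema_version = 1L,
    name = "base",
    n_patients = as.integer(n_patients),
    seed = as.integer(seed),
    subset = "all",
    costs = list(
      allogeneic_unit_cost = 320,
      autologous_collection_cost = 500,
      epo_dose_cost = 200,
      hospital_day_cost = 300,
      pneumonia_cost = 5000
    ),
    clinical = list(
      transfusion_trigger = 8.5,
      cardiac_trigger_shift = 1.0,
      transfuse_at_equality = FALSE,
      hb_per_unit = 1.0,
      blood_loss_mean_hip = 3.3,
      blood_loss_mean_knee = 3.5,
      blood_loss_sd = 1.0,
      asa_loss_factor = 1.05,
      age_loss_factor = 1.05,
      revision_loss_factor = 1.25,
      old_age_threshold = 75,
      ebv_per_kg = 65,
      weight_floor = 35,
      pad_hb_decrement_mean = 1.2,
      pad_hb_decrement_sd = 0.83,
      pad_units = 2L,
      pad_min_hb = 11.0,
      epo_regimen = list(
        termination_hb = 13.3,
        max_injections = 3L,
        per_injection_increment_mean = 1.0,
        per_injection_increment_sd = 0.6,
        day_of_surgery_dose_counts_cost_only = FALSE
      ),
      los_transfusion_factor = 1.2,
      los_infection_factor = 1.6,
      los_both_factor = 1.9,
      los_age_factor = 1.0,
      p_pneumonia_base = 0.008,
      p_pneumonia_transfused = 0.016,
      p_infection_base = 0.02,
      p_infection_transfused = 0.04,
      ra_epo_attenuation = 0.8,
      rheumatoid_risk_hip = 0.03,
      rheumatoid_risk_knee = 0.05,
      cardiac_history_prob = 0.15
    ),
    hb_weibull_female = list(shape = 9, scale = 14.5, location = 0),
    hb_weibull_male = list(shape = 10, scale = 15.3, location = 0),
    population = NULL
  )
  class(cfg) <- "bloodsim_config"
  cfg
}

#' Validate a model configuration
#'
#' Checks range and consistency invariants: costs non-negative, the
#' transfusion trigger within [7, 10], probabilities within [0, 1],
#' length-of-stay factors at least 1, a positive epoetin regimen, and a
#' schema-valid population table when one is attached.
#'
#' @param config a \code{bloodsim_config}.
#' @return \code{config}, invisibly, if valid; otherwise an error naming the
#'   offending field and bound.
#' @export
validate_config <- function(config) {
  fail <- function(field, msg) {
    stop(sprintf("invalid config field '%s': %s", field, msg), call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

  if (!is.list(config)) stop("config must be a list", call. = FALSE)
  if (!num1(config$n_patients) || config$n_patients < 1)
    fail("n_patients", "must be >= 1")
  if (!num1(config$seed)) fail("seed", "must be a single integer")
  if (!config$subset %in% c("all", "revision"))
    fail("subset", "must be 'all' or 'revision'")

  co <- config$costs
  for (f in c("allogeneic_unit_cost", "autologous_collection_cost",
              "epo_dose_cost", "hospital_day_cost", "pneumonia_cost")) {
    if (!num1(co[[f]]) || co[[f]] < 0)
      fail(paste0("costs.", f), "must be >= 0")
  }

  cl <- config$clinical
  if (!num1(cl$transfusion_trigger) ||
      cl$transfusion_trigger < 7 || cl$transfusion_trigger > 10)
    fail("clinical.transfusion_trigger", "must be in [7, 10]")
  for (f in c("p_pneumonia_base", "p_pneumonia_transfused",
              "p_infection_base", "p_infection_transfused",
              "rheumatoid_risk_hip", "rheumatoid_risk_knee",
              "cardiac_history_prob")) {
    if (!num1(cl[[f]]) || cl[[f]] < 0 || cl[[f]] > 1)
      fail(paste0("clinical.", f), "must be a probability in [0, 1]")
  }
  for (f in c("los_transfusion_factor", "los_infection_factor",
              "los_both_factor", "los_age_factor")) {
    if (!num1(cl[[f]]) || cl[[f]] < 1)
      fail(paste0("clinical.", f), "must be a multiplier >= 1")
  }
  for (f in c("hb_per_unit", "ebv_per_kg", "weight_floor",
              "blood_loss_mean_hip", "blood_loss_mean_knee")) {
    if (!num1(cl[[f]]) || cl[[f]] <= 0)
      fail(paste0("clinical.", f), "must be > 0")
  }
  if (!num1(cl$blood_loss_sd) || cl$blood_loss_sd < 0)
    fail("clinical.blood_loss_sd", "must be >= 0")
  for (f in c("asa_loss_factor", "age_loss_factor", "revision_loss_factor")) {
    if (!num1(cl[[f]]) || cl[[f]] < 1)
      fail(paste0("clinical.", f), "must be a multiplier >= 1")
  }
  if (!num1(cl$ra_epo_attenuation) ||
      cl$ra_epo_attenuation <= 0 || cl$ra_epo_attenuation > 1)
    fail("clinical.ra_epo_attenuation", "must be in (0, 1]")
  if (!num1(cl$pad_units) || cl$pad_units < 0)
    fail("clinical.pad_units", "must be >= 0")
  if (!num1(cl$pad_hb_decrement_sd) || cl$pad_hb_decrement_sd < 0)
    fail("clinical.pad_hb_decrement_sd", "must be >= 0")

  reg <- cl$epo_regimen
  if (!num1(reg$termination_hb) || reg$termination_hb <= 0)
    fail("clinical.epo_regimen.termination_hb", "must be > 0")
  if (!num1(reg$max_injections) || reg$max_injections < 1)
    fail("clinical.epo_regimen.max_injections", "must be >= 1")
  if (!num1(reg$per_injection_increment_sd) || reg$per_injection_increment_sd < 0)
    fail("clinical.epo_regimen.per_injection_increment_sd", "must be >= 0")

  for (f in c("hb_weibull_female", "hb_weibull_male")) {
    w <- config[[f]]
    if (!num1(w$shape) || w$shape <= 0 || !num1(w$scale) || w$scale <= 0)
      fail(f, "shape and scale must be > 0")
  }

  if (!is.null(config$population)) validate_population(config$population)
  invisible(config)
}

## recursive override of defaults, erroring on keys the schema does not have
merge_config <- function(base, override, path = character()) {
  for (key in names(override)) {
    here <- paste(c(path, key), collapse = ".")
    if (!key %in% names(base)) {
      stop(sprintf("unknown config key '%s'", here), call. = FALSE)
    }
    if (is.list(base[[key]]) && !is.data.frame(base[[key]])) {
      if (!is.list(override[[key]]))
        stop(sprintf("config key '%s' must be a mapping", here), call. = FALSE)
      base[[key]] <- merge_config(base[[key]], override[[key]], c(path, key))
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Load a model configuration from a YAML or JSON file
#'
#' Reads a (possibly partial) configuration document, fills every omitted
#' field with its base-case default, and validates the result. An empty file
#' yields the full base-case configuration. The \code{population} field, if
#' present, must be the path of a population-table CSV (resolved relative to
#' the config file) and is loaded with [read_population()].
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return A validated \code{bloodsim_config}.
#' @export
#' @examples
#' f <- system.file("extdata", "example-config.yaml", package = "bloodsim")
#' cfg <- load_config(f)
#' cfg$clinical$transfusion_trigger
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(doc)) doc <- list()
  if (!is.list(doc)) stop("config file must contain a mapping", call. = FALSE)

  pop <- NULL
  if (!is.null(doc$population) && is.character(doc$population)) {
    pop_path <- doc$population
    if (!file.exists(pop_path))
      pop_path <- file.path(dirname(path), doc$population)
    pop <- read_population(pop_path)
    doc$population <- NULL
  }
  cfg <- merge_config(default_config(), doc)
  if (!is.null(pop)) cfg$population <- pop
  class(cfg) <- "bloodsim_config"
  validate_config(cfg)
  cfg
}

#' Serialize a configuration to YAML or JSON
#'
#' Inverse of [load_config()] up to the population table, which is written to
#' a sibling CSV and referenced by file name. Reloading the written file
#' reproduces an equal configuration.
#'
#' @param config a \code{bloodsim_config}.
#' @param path output file; format chosen by extension (\code{.json} or YAML
#'   otherwise).
#' @return \code{path}, invisibly.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  out <- unclass(config)
  if (!is.null(out$population)) {
    pop_file <- paste0(tools::file_path_sans_ext(basename(path)),
                       "_population.csv")
    write_population(out$population, file.path(dirname(path), pop_file))
    out$population <- pop_file
  } else {
    out$population <- NULL
  }
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}

#' @export
print.bloodsim_config <- function(x, ...) {
  cat("<bloodsim_config>", x$name, "\n")
  cat(sprintf("  n_patients: %d   seed: %d   subset: %s\n",
              x$n_patients, x$seed, x$subset))
  cat(sprintf("  trigger: %.1f g/dl (+%.1f cardiac)   Hb/unit: %.1f g/dl\n",
              x$clinical$transfusion_trigger, x$clinical$cardiac_trigger_shift,
              x$clinical$hb_per_unit))
  cat(sprintf("  blood loss: hip %.1f / knee %.1f g/dl (sd %.1f)\n",
              x$clinical$blood_loss_mean_hip, x$clinical$blood_loss_mean_knee,
              x$clinical$blood_loss_sd))
  reg <- x$clinical$epo_regimen
  cat(sprintf("  EPO: stop at %.1f g/dl, max %d doses; PAD: %d units if Hb >= %.1f\n",
              reg$termination_hb, reg$max_injections,
              x$clinical$pad_units, x$clinical$pad_min_hb))
  cat(sprintf("  costs (EUR): RBC %g/unit, PAD %g, EPO %g/dose, day %g, pneumonia %g\n",
              x$costs$allogeneic_unit_cost, x$costs$autologous_collection_cost,
              x$costs$epo_dose_cost, x$costs$hospital_day_cost,
              x$costs$pneumonia_cost))
  cat(sprintf("  population: %s\n",
              if (is.null(x$population)) "synthetic default"
              else sprintf("%d cells", nrow(x$population))))
  invisible(x)
}
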