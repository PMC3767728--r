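#' Sensitivity-analysis scenario grid
#'
#' Expands a base configuration into the named scenario set of the
#' sensitivity analysis: alternative transfusion triggers (8.0, 9.0), the
#' revision-surgery subgroup, the liberal epoetin protocol (termination
#' 15 g/dl, up to 4 injections, last dose on the day of surgery counted for
#' cost only), alternative autologous-donation Hb decrements, reduced
#' blood-loss variants, the length-of-stay inflation varied across its
#' confidence range, each unit cost varied by +/-25% (plus all costs
#' jointly), and a zero-correlation bound in which the ASA, old-age and
#' revision blood-loss multipliers are switched off.
#'
#' @param base a validated \code{bloodsim_config}.
#' @return A named list of scenario specifications; each element has
#'   \code{$name} and \code{$overrides}, a named list mapping dotted
#'   parameter paths to replacement values. Apply with [apply_scenario()].
#' @export
#' @examples
#' sc <- build_scenarios(default_config())
#' names(sc)
#' sc$zero_correlation$overrides
build_scenarios <- function(base) {
  validate_config(base)
  scenario <- function(name, overrides = list()) {
    structure(list(name = name, overrides = overrides),
              class = "bloodsim_scenario")
  }
  out <- list(
    base = scenario("base"),
    trigger_8.0 = scenario("trigger_8.0",
      list("clinical.transfusion_trigger" = 8.0)),
    trigger_9.0 = scenario("trigger_9.0",
      list("clinical.transfusion_trigger" = 9.0)),
    revision_only = scenario("revision_only", list("subset" = "revision")),
    epo_weber = scenario("epo_weber", list(
      "clinical.epo_regimen.termination_hb" = 15,
      "clinical.epo_regimen.max_injections" = 4L,
      "clinical.epo_regimen.day_of_surgery_dose_counts_cost_only" = TRUE))
  )
  for (d in c(1.16, 1.05, 0.8, 0.67)) {
    nm <- sprintf("pad_effect_%.2f", d)
    out[[nm]] <- scenario(nm, list("clinical.pad_hb_decrement_mean" = d))
  }
  loss <- list(blood_loss_low = c(hip = 3.1, knee = 2.9),
               blood_loss_medium = c(hip = 2.8, knee = 2.5),
               blood_loss_minimal = c(hip = 2.1, knee = 1.9))
  for (nm in names(loss)) {
    out[[nm]] <- scenario(nm, list(
      "clinical.blood_loss_mean_hip" = unname(loss[[nm]]["hip"]),
      "clinical.blood_loss_mean_knee" = unname(loss[[nm]]["knee"])))
  }
  for (pct in c(5, 11, 29, 35)) {
    nm <- sprintf("los_plus%d", pct)
    out[[nm]] <- scenario(nm,
      list("clinical.los_transfusion_factor" = 1 + pct / 100))
  }
  cost_paths <- list(
    cost_epo = "costs.epo_dose_cost",
    cost_rbc = "costs.allogeneic_unit_cost",
    cost_pad = "costs.autologous_collection_cost")
  for (nm in names(cost_paths)) {
    p <- cost_paths[[nm]]
    v <- config_get(base, p)
    out[[paste0(nm, "_up")]] <- scenario(paste0(nm, "_up"),
                                         stats::setNames(list(v * 1.25), p))
    out[[paste0(nm, "_down")]] <- scenario(paste0(nm, "_down"),
                                           stats::setNames(list(v * 0.75), p))
  }
  all_costs <- paste0("costs.", c("allogeneic_unit_cost",
                                  "autologous_collection_cost",
                                  "epo_dose_cost", "hospital_day_cost",
                                  "pneumonia_cost"))
  for (fac in c(up = 1.25, down = 0.75)) {
    dir <- if (fac > 1) "up" else "down"
    ov <- lapply(all_costs, function(p) config_get(base, p) * fac)
    names(ov) <- all_costs
    out[[paste0("cost_total_", dir)]] <- scenario(paste0("cost_total_", dir), ov)
  }
  out$zero_correlation <- scenario("zero_correlation", list(
    "clinical.asa_loss_factor" = 1.0,
    "clinical.age_loss_factor" = 1.0,
    "clinical.revision_loss_factor" = 1.0))
  out
}

config_get <- function(config, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- config
  for (k in keys) {
    if (!is.list(node) || !k %in% names(node))
      stop(sprintf("config path '%s' does not exist", path), call. = FALSE)
    node <- node[[k]]
  }
  node
}

config_set <- function(config, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  set_rec <- function(node, keys) {
    k <- keys[[1]]
    if (!is.list(node) || !k %in% names(node))
      stop(sprintf("config path '%s' does not exist", path), call. = FALSE)
    if (length(keys) == 1L) node[[k]] <- value
    else node[[k]] <- set_rec(node[[k]], keys[-1])
    node
  }
  set_rec(config, keys)
}

#' Apply a scenario to a base configuration
#'
#' Returns a copy of \code{base} with the scenario's overrides applied and
#' revalidated; \code{base} itself is never modified and repeated application
#' yields identical configurations.
#'
#' @param base a validated \code{bloodsim_config}.
#' @param scenario one element of [build_scenarios()], or any list with
#'   \code{$name} and \code{$overrides} of dotted paths.
#' @return A new \code{bloodsim_config} named after the scenario.
#' @export
apply_scenario <- function(base, scenario) {
  cfg <- base
  for (path in names(scenario$overrides)) {
    cfg <- config_set(cfg, path, scenario$overrides[[path]])
  }
  cfg$name <- scenario$name
  class(cfg) <- "bloodsim_config"
  validate_config(cfg)
  cfg
}
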