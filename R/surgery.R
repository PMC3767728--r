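#' Effective transfusion trigger for a patient
#'
#' A history of cardiac events raises the transfusion trigger by a fixed
#' shift (1 g/dl Hb in the base case), regardless of the trigger value in
#' use.
#'
#' @param base_trigger trigger in g/dl Hb; must be positive.
#' @param cardiac_history logical flag (vectorized).
#' @param shift trigger shift in g/dl Hb.
#' @return Effective trigger(s) in g/dl.
#' @export
#' @examples
#' effective_trigger(8.5, TRUE) # 9.5
effective_trigger <- function(base_trigger, cardiac_history, shift = 1.0) {
  if (any(base_trigger <= 0)) stop("trigger must be > 0", call. = FALSE)
  base_trigger + shift * as.numeric(cardiac_history)
}

#' Post-surgery hemoglobin
#'
#' Adjusted preoperative Hb minus the surgical blood loss (both in g/dl),
#' floored at 0.
#'
#' @param preop_hb_adjusted arm-adjusted preoperative Hb in g/dl.
#' @param blood_loss_hb surgical loss as a positive Hb magnitude.
#' @return Post-surgery Hb in g/dl (vectorized).
#' @export
postoperative_hb <- function(preop_hb_adjusted, blood_loss_hb) {
  pmax(0, preop_hb_adjusted - blood_loss_hb)
}

#' Red-cell units needed to meet the transfusion trigger
#'
#' A patient at or above the trigger needs no transfusion; otherwise enough
#' whole units are given to bring the hemoglobin to a level that meets or
#' exceeds the trigger, i.e. \code{ceiling((trigger - postop) / hb_per_unit)}.
#' The exact-equality boundary is configurable: with
#' \code{transfuse_at_equality} a patient landing exactly on the trigger
#' receives one unit instead of none.
#'
#' @param postop_hb post-surgery Hb in g/dl (vectorized).
#' @param trigger effective trigger in g/dl.
#' @param hb_per_unit Hb gain per transfused unit in g/dl; must be positive.
#' @param transfuse_at_equality boundary semantics switch.
#' @return Integer unit counts.
#' @export
#' @examples
#' units_required(7.2, 8.5) # 2
units_required <- function(postop_hb, trigger, hb_per_unit = 1.0,
                           transfuse_at_equality = FALSE) {
  if (hb_per_unit <= 0) stop("hb_per_unit must be > 0", call. = FALSE)
  units <- ifelse(postop_hb >= trigger, 0,
                  ceiling((trigger - postop_hb) / hb_per_unit))
  if (transfuse_at_equality) {
    units <- ifelse(postop_hb == trigger, pmax(1, units), units)
  }
  as.integer(units)
}

#' Split required units between autologous stock and allogeneic supply
#'
#' Banked autologous units are used first; any remaining demand is met with
#' allogeneic blood.
#'
#' @param units_needed total units required (vectorized).
#' @param autologous_available banked autologous units.
#' @return A list with integer vectors \code{autologous} and
#'   \code{allogeneic}.
#' @export
transfuse <- function(units_needed, autologous_available) {
  if (any(units_needed < 0)) stop("units_needed must be >= 0", call. = FALSE)
  auto <- pmin(units_needed, autologous_available)
  list(autologous = as.integer(auto),
       allogeneic = as.integer(units_needed - auto))
}

#' Sample nosocomial infection events
#'
#' Bernoulli draw at an elevated probability for patients who received any
#' (allogeneic or autologous) transfusion.
#'
#' @param transfused logical vector.
#' @param clinical the \code{clinical} block of a \code{bloodsim_config}.
#' @return Logical vector of infection events.
#' @export
sample_infection <- function(transfused, clinical) {
  p <- ifelse(transfused, clinical$p_infection_transfused,
              clinical$p_infection_base)
  stats::runif(length(transfused)) < p
}

#' Sample pneumonia events
#'
#' Background pneumonia risk of 0.8% doubled to 1.6% for transfused
#' patients in the base case; costed per event.
#'
#' @inheritParams sample_infection
#' @return Logical vector of pneumonia events.
#' @export
sample_pneumonia <- function(transfused, clinical) {
  p <- ifelse(transfused, clinical$p_pneumonia_transfused,
              clinical$p_pneumonia_base)
  stats::runif(length(transfused)) < p
}

#' Length of stay after event adjustment
#'
#' The DRG base stay is inflated by 20% after a transfusion, 60% after an
#' infection, and 90% when both occur (base-case factors), plus a
#' configurable age multiplier (1.0, i.e. inactive, by default). Days are
#' kept fractional for costing.
#'
#' @param base_los base length of stay in days; must be positive.
#' @param transfused,infection logical event flags (vectorized).
#' @param clinical the \code{clinical} block of a \code{bloodsim_config}.
#' @return Length of stay in days.
#' @export
#' @examples
#' length_of_stay(10, TRUE, TRUE, default_config()$clinical) # 19
length_of_stay <- function(base_los, transfused, infection, clinical) {
  if (any(base_los <= 0)) stop("base_los must be > 0", call. = FALSE)
  factor <- ifelse(transfused & infection, clinical$los_both_factor,
            ifelse(transfused, clinical$los_transfusion_factor,
            ifelse(infection, clinical$los_infection_factor, 1.0)))
  base_los * factor * clinical$los_age_factor
}
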