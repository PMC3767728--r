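#' Allogeneic-only arm: no preoperative Hb adjustment
#'
#' The no-blood-conservation strategy leaves the baseline hemoglobin
#' untouched and banks no autologous units.
#'
#' @param profile a \code{bloodsim_patient}.
#' @return An arm state list (class \code{bloodsim_arm}): \code{arm},
#'   \code{preop_hb_adjusted}, \code{autologous_units_available},
#'   \code{epo_doses_given}, \code{epo_doses_effective},
#'   \code{pad_applicable}, \code{hb_change}.
#' @export
apply_abt <- function(profile) {
  structure(list(
    arm = "ABT",
    preop_hb_adjusted = profile$baseline_hb,
    autologous_units_available = 0L,
    epo_doses_given = 0L,
    epo_doses_effective = 0L,
    pad_applicable = FALSE,
    hb_change = 0
  ), class = "bloodsim_arm")
}

#' Preoperative autologous donation arm
#'
#' Patients with baseline Hb at or above the donation threshold (11 g/dl)
#' donate two units before surgery; their hemoglobin at the time of surgery
#' is reduced by a normally distributed amount (base case mean 1.2, SD
#' 0.83 g/dl, drawn once for the whole donation). Patients below the
#' threshold are not eligible and behave exactly like the allogeneic-only
#' arm.
#'
#' @param profile a \code{bloodsim_patient}.
#' @param clinical the \code{clinical} block of a \code{bloodsim_config}.
#' @return An arm state list; \code{hb_change} holds the (negative)
#'   realized decrement when applicable.
#' @export
apply_pad <- function(profile, clinical) {
  if (profile$baseline_hb < clinical$pad_min_hb) {
    st <- apply_abt(profile)
    st$arm <- "PAD"
    return(st)
  }
  dec <- stats::rnorm(1L, clinical$pad_hb_decrement_mean,
                      clinical$pad_hb_decrement_sd)
  structure(list(
    arm = "PAD",
    preop_hb_adjusted = profile$baseline_hb - dec,
    autologous_units_available = as.integer(clinical$pad_units),
    epo_doses_given = 0L,
    epo_doses_effective = 0L,
    pad_applicable = TRUE,
    hb_change = -dec
  ), class = "bloodsim_arm")
}

#' Preoperative epoetin alfa arm
#'
#' 40,000 IU injections are given while the running hemoglobin is below the
#' regimen's termination level (13.3 g/dl base case) and fewer than
#' \code{max_injections} doses have been given; the check precedes each
#' dose, so a patient entering at or above termination receives nothing.
#' Each dose adds a 0-truncated normal Hb increment, attenuated
#' multiplicatively for rheumatoid patients. Under the liberal protocol
#' flag (\code{day_of_surgery_dose_counts_cost_only}) the last administered
#' dose falls on the day of surgery: it is counted (and costed) but its
#' increment cannot act before surgery and is withdrawn from the adjusted
#' hemoglobin.
#'
#' @param profile a \code{bloodsim_patient}.
#' @param clinical the \code{clinical} block of a \code{bloodsim_config}.
#' @return An arm state list; \code{hb_change} is the realized preoperative
#'   Hb increase and \code{epo_doses_given}/\code{epo_doses_effective} the
#'   dose counts for costing and reporting.
#' @export
apply_epo <- function(profile, clinical) {
  reg <- clinical$epo_regimen
  hb <- profile$baseline_hb
  given <- 0L
  last_inc <- 0
  while (hb < reg$termination_hb && given < reg$max_injections) {
    inc <- max(0, stats::rnorm(1L, reg$per_injection_increment_mean,
                               reg$per_injection_increment_sd))
    if (profile$rheumatoid) inc <- inc * clinical$ra_epo_attenuation
    hb <- hb + inc
    last_inc <- inc
    given <- given + 1L
  }
  effective <- given
  if (isTRUE(reg$day_of_surgery_dose_counts_cost_only) && given > 0L) {
    hb <- hb - last_inc
    effective <- given - 1L
  }
  structure(list(
    arm = "EPO",
    preop_hb_adjusted = hb,
    autologous_units_available = 0L,
    epo_doses_given = given,
    epo_doses_effective = effective,
    pad_applicable = FALSE,
    hb_change = hb - profile$baseline_hb
  ), class = "bloodsim_arm")
}
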