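#' Cost one arm's surgical episode
#'
#' Converts the episode's events into the per-patient cost breakdown:
#' epoetin doses at the per-dose price, allogeneic units at the per-unit
#' price, a flat autologous collection charge for every donation-eligible
#' patient (whether or not the banked units are reinfused), the hospital
#' stay at the per-day rate, and a flat pneumonia treatment charge per
#' event. All arguments after the first are vectorized.
#'
#' @param costs the \code{costs} block of a \code{bloodsim_config}.
#' @param epo_doses_given epoetin doses administered (costed even when a
#'   day-of-surgery dose had no Hb effect).
#' @param allogeneic_units allogeneic units transfused.
#' @param pad_applicable logical; donation performed.
#' @param los length of stay in days (fractional allowed).
#' @param pneumonia logical pneumonia event.
#' @return A \code{data.frame} with columns \code{epo_cost},
#'   \code{transfusion_allogeneic_cost}, \code{pad_collection_cost},
#'   \code{los_cost}, \code{pneumonia_cost}, \code{total_cost} (EUR).
#' @export
#' @examples
#' cost_episode(default_config()$costs, 0, 2, FALSE, 12, FALSE)$total_cost
cost_episode <- function(costs, epo_doses_given, allogeneic_units,
                         pad_applicable, los, pneumonia) {
  as.data.frame(cost_components(costs, epo_doses_given, allogeneic_units,
                                pad_applicable, los, pneumonia))
}

## list-of-vectors form used by the simulation engine
cost_components <- function(costs, epo_doses_given, allogeneic_units,
                            pad_applicable, los, pneumonia) {
  if (any(epo_doses_given < 0) || any(allogeneic_units < 0) || any(los < 0))
    stop("episode inputs must be >= 0", call. = FALSE)
  epo <- epo_doses_given * costs$epo_dose_cost
  allo <- allogeneic_units * costs$allogeneic_unit_cost
  pad <- as.numeric(pad_applicable) * costs$autologous_collection_cost
  stay <- los * costs$hospital_day_cost
  pneu <- as.numeric(pneumonia) * costs$pneumonia_cost
  list(
    epo_cost = epo,
    transfusion_allogeneic_cost = allo,
    pad_collection_cost = pad,
    los_cost = stay,
    pneumonia_cost = pneu,
    total_cost = epo + allo + pad + stay + pneu
  )
}

#' Paired incremental cost between two strategy arms
#'
#' Because the arms are clones of the same patients, the incremental cost
#' is the mean of the per-patient paired differences (reference minus
#' comparator) with its paired standard error, SD(differences)/sqrt(n).
#'
#' @param reference_costs,comparator_costs equal-length cost vectors in
#'   patient order.
#' @return Named vector \code{mean}, \code{se}, \code{sd}, \code{n}.
#' @export
#' @examples
#' incremental_cost(c(100, 200), c(90, 190))
incremental_cost <- function(reference_costs, comparator_costs) {
  if (length(reference_costs) != length(comparator_costs))
    stop("cost vectors must be paired (equal length)", call. = FALSE)
  if (length(reference_costs) < 2)
    stop("need at least 2 paired observations", call. = FALSE)
  d <- reference_costs - comparator_costs
  n <- length(d)
  c(mean = mean(d), se = stats::sd(d) / sqrt(n), sd = stats::sd(d), n = n)
}
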