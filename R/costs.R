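# Cost engine: intervention provision, schooling by placement mix, and the
# regression-predicted social care + medical costs; assembled by category
# and perspective.  The health/social-care ("nhs_social") perspective counts
# intervention and social/medical (and adult care in the lifetime scenario);
# the public-sector perspective adds schooling.

#' Per-cycle intervention cost flow
#'
#' ABA-based intervention costs accrue at `cost_aba_annual / 12` per month
#' for the treatment duration (default 24 months); TAU nursery provision at
#' `cost_tau_annual / 12` during its costing window
#' (`settings$tau_cost_window_months`, default 24).
#'
#' @param arm `"ABA"` or `"TAU"`.
#' @param params an [aba_parameters()] object.
#' @param horizon_months flow length (defaults to the settings horizon).
#' @return numeric vector of monthly costs.
#' @export
intervention_cost_flow <- function(arm = c("ABA", "TAU"), params,
                                   horizon_months = NULL) {
  arm <- match.arg(arm)
  s <- params$settings
  H <- if (is.null(horizon_months)) s$horizon_months else horizon_months
  t <- seq_len(H) - 1L
  if (arm == "ABA") {
    ifelse(t < s$treatment_duration_months, param_mean(params, "cost_aba_annual") / 12, 0)
  } else {
    ifelse(t < s$tau_cost_window_months, param_mean(params, "cost_tau_annual") / 12, 0)
  }
}

#' Annual social care and medical cost prediction
#'
#' Regression of annual cost on cohort scores,
#' `max(0, intercept + b_vabs * vabs + b_iq * iq)`; the floor guards against
#' negative predictions for high-functioning cohorts.
#'
#' @param iq,vabs cohort mean scores (vectorised).
#' @param coef named vector/list with `socmed_intercept`, `socmed_vabs`,
#'   `socmed_iq`.
#' @return annual cost(s), GBP.
#' @export
socmed_annual <- function(iq, vabs, coef = param_means(aba_parameters())) {
  coef <- as.list(coef)
  pmax(0, coef$socmed_intercept + coef$socmed_vabs * vabs + coef$socmed_iq * iq)
}

#' Per-cycle schooling cost flow
#'
#' Zero during pre-school; during the primary phase the placement-weighted
#' mean of the three annual school costs (divided by 12), and analogously
#' with the secondary mix from `primary_end_months` on.
#'
#' @param mix_primary,mix_secondary placement probability vectors
#'   `(mainstream, supported, special)`.
#' @param params an [aba_parameters()] object.
#' @param horizon_months flow length; schooling runs from
#'   `preschool_end_months` to the childhood horizon even when the flow is
#'   longer (lifetime scenario).
#' @return numeric vector of monthly costs.
#' @export
schooling_cost_flow <- function(mix_primary, mix_secondary, params,
                                horizon_months = NULL) {
  s <- params$settings
  H <- if (is.null(horizon_months)) s$horizon_months else horizon_months
  m <- param_means(params)
  unit <- c(m[["school_mainstream"]], m[["school_supported"]], m[["school_special"]])
  t <- seq_len(H) - 1L
  flow <- numeric(H)
  flow[t >= s$preschool_end_months & t < s$primary_end_months] <- sum(mix_primary * unit) / 12
  flow[t >= s$primary_end_months & t < s$horizon_months] <- sum(mix_secondary * unit) / 12
  flow
}

#' Discounted cost breakdown for one arm
#'
#' Accumulates the intervention, schooling and social/medical flows (each
#' weighted by the survival fraction) with mid-cycle discounting, and
#' assembles per-perspective totals.
#'
#' @param traj a `cea_trajectory` for the arm.
#' @param mix_primary,mix_secondary placement mixes for the arm.
#' @param params an [aba_parameters()] object.
#' @return object of class `cost_breakdown`: list with `intervention`,
#'   `schooling`, `social_medical`, `adult_care` (zero here; filled by the
#'   lifetime scenario) and a `total(perspective)` accessor via
#'   [cost_total()].
#' @export
total_costs <- function(traj, mix_primary, mix_secondary, params) {
  stopifnot(inherits(traj, "cea_trajectory"))
  s <- params$settings
  m <- param_means(params)
  H <- s$horizon_months
  i <- seq_len(H)
  surv <- traj$survival[i]
  r <- s$discount_rate_annual; mode <- s$discounting
  arm <- attr(traj, "arm")
  int <- accumulate(intervention_cost_flow(arm, params, H) * surv, r, mode)
  sch <- accumulate(schooling_cost_flow(mix_primary, mix_secondary, params, H) * surv, r, mode)
  sm <- accumulate(socmed_annual(traj$iq[i], traj$vabs[i], m) / 12 * surv, r, mode)
  structure(list(intervention = int, schooling = sch, social_medical = sm,
                 adult_care = 0), class = "cost_breakdown")
}

#' Total cost under a perspective
#'
#' @param costs a `cost_breakdown`.
#' @param perspective `"nhs_social"` (intervention + social/medical + adult
#'   care) or `"public_sector"` (additionally schooling).
#' @return total discounted cost.
#' @export
cost_total <- function(costs, perspective = c("public_sector", "nhs_social")) {
  perspective <- match.arg(perspective)
  base <- costs$intervention + costs$social_medical + costs$adult_care
  if (perspective == "public_sector") base + costs$schooling else base
}
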