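# Cohort engine: monthly evolution of cohort mean IQ and VABS per arm, plus
# the discounting/accumulation machinery shared by the QALY and cost engines.

#' TAU score trajectory
#'
#' Cohort mean score under treatment as usual: linear drift from baseline at
#' the natural-history rate, `score0 + annual_change * t/12`.
#'
#' @param t month(s) since model start (vectorised).
#' @param score0 baseline score.
#' @param annual_change score change per year (negative for decline).
#' @return score at month `t`.
#' @export
tau_score <- function(t, score0, annual_change) {
  stopifnot(all(t >= 0))
  score0 + annual_change * t / 12
}

#' Treatment effect trajectory
#'
#' Additive ABA-vs-TAU score difference at month `t`: a linear ramp from 0
#' at baseline through the one-year effect at month 12 to the two-year
#' effect at month 24.  Beyond the end of treatment the effect either
#' persists unchanged (`durability = "optimistic"`) or decays linearly to
#' zero at `washout_end` months (`"pessimistic"`), remaining zero after.
#'
#' @param t month(s) since model start (vectorised).
#' @param effect_y1,effect_y2 effects at one and two years.
#' @param durability `"optimistic"` or `"pessimistic"`.
#' @param washout_end month at which the pessimistic effect reaches zero
#'   (default 84, i.e. age 10 for a cohort starting at age 3).
#' @return effect at month `t`.
#' @export
treatment_effect <- function(t, effect_y1, effect_y2,
                             durability = c("optimistic", "pessimistic"),
                             washout_end = 84) {
  durability <- match.arg(durability)
  stopifnot(all(t >= 0))
  if (durability == "pessimistic" && washout_end <= 24)
    stop("pessimistic washout must end after month 24")
  eff <- ifelse(t <= 12, effect_y1 * t / 12,
         ifelse(t <= 24, effect_y1 + (effect_y2 - effect_y1) * (t - 12) / 12,
                effect_y2))
  if (durability == "pessimistic") {
    late <- t > 24
    eff[late] <- effect_y2 * pmax(0, washout_end - t[late]) / (washout_end - 24)
  }
  eff
}

#' Build a cohort trajectory for one arm
#'
#' States at months 0..horizon: age, mean IQ, mean VABS (ABA = TAU +
#' treatment effect), constant ADOS, and the survival fraction from the
#' mortality model.
#'
#' @param params an [aba_parameters()] object.
#' @param arm `"TAU"` or `"ABA"`.
#' @param durability `"optimistic"` or `"pessimistic"` (ignored for TAU).
#' @param horizon_months horizon override (defaults to the settings value;
#'   the lifetime scenario extends it).
#' @return object of class `cea_trajectory`: a data frame with columns
#'   `month`, `age_months`, `iq`, `vabs`, `ados`, `survival` and attributes
#'   `arm`, `durability`.
#' @export
build_trajectory <- function(params, arm = c("TAU", "ABA"),
                             durability = c("optimistic", "pessimistic"),
                             horizon_months = NULL) {
  arm <- match.arg(arm); durability <- match.arg(durability)
  stopifnot(inherits(params, "aba_parameters"))
  s <- params$settings
  H <- if (is.null(horizon_months)) s$horizon_months else horizon_months
  m <- param_means(params)
  t <- 0:H
  iq <- tau_score(t, m["iq0"], m["d_iq_per_year"])
  vabs <- tau_score(t, m["vabs0"], m["d_vabs_per_year"])
  if (arm == "ABA") {
    iq <- iq + treatment_effect(t, m["eff_y1_iq"], m["eff_y2_iq"], durability,
                                s$pessimistic_washout_end_months)
    vabs <- vabs + treatment_effect(t, m["eff_y1_vabs"], m["eff_y2_vabs"], durability,
                                    s$pessimistic_washout_end_months)
  }
  if (any(iq <= 0)) stop("model error: non-positive IQ along the trajectory")
  surv <- survival_curve(default_mortality(params), s$start_age_years, H)
  out <- data.frame(month = t, age_months = m["age_months"] + t, iq = unname(iq),
                    vabs = unname(vabs), ados = unname(m["ados0"]), survival = surv)
  structure(out, arm = arm, durability = durability, class = c("cea_trajectory", "data.frame"))
}

#' Discount factor at a given month
#'
#' Continuous-in-months compounding, `(1 + rate)^(-t/12)`.
#'
#' @param t month(s) since model start.
#' @param rate annual discount rate (> -1).
#' @return discount factor(s).
#' @export
discount_factor <- function(t, rate) {
  stopifnot(all(t >= 0), rate > -1)
  (1 + rate)^(-t / 12)
}

# per-cycle mid-cycle discount factors for a horizon; "annual" steps the
# factor once per model year (half-year centred), matching a yearly-cycle
# implementation aggregated to months.
.cycle_discount <- function(horizon, rate, mode = c("monthly", "annual")) {
  mode <- match.arg(mode)
  t <- seq_len(horizon) - 1
  if (mode == "monthly") discount_factor(t + 0.5, rate)
  else (1 + rate)^(-(floor(t / 12) + 0.5))
}

#' Accumulate discounted per-cycle flows with half-cycle correction
#'
#' Each cycle's flow is discounted at its midpoint: the total is
#' `sum(values[t+1] * (1 + rate)^(-(t + 0.5)/12))` over cycles
#' `t = 0, ..., length(values) - 1`.
#'
#' @param values per-cycle (monthly) amounts.
#' @param rate annual discount rate.
#' @param mode `"monthly"` (default) or `"annual"` step discounting.
#' @return discounted total.
#' @export
accumulate <- function(values, rate, mode = c("monthly", "annual")) {
  sum(values * .cycle_discount(length(values), rate, match.arg(mode)))
}

#' @export
print.cea_trajectory <- function(x, ...) {
  cat(sprintf("Cohort trajectory: arm %s (%s durability), %d months\n",
              attr(x, "arm"), attr(x, "durability"), nrow(x) - 1L))
  cat(sprintf("  IQ %.2f -> %.2f, VABS %.2f -> %.2f, survival %.4f at end\n",
              x$iq[1], x$iq[nrow(x)], x$vabs[1], x$vabs[nrow(x)], x$survival[nrow(x)]))
  invisible(x)
}
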