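# Utility and QALY engine, including the mortality model.

#' Child utility regression
#'
#' Linear utility algorithm on age, age squared, ADOS severity, log IQ and
#' VABS: `u = c + b_age*age + b_age2*age^2 + b_ados*ados + b_logiq*log(iq)
#' + b_vabs*vabs`.  The linear model can exceed 1 for high-functioning
#' states; an optional cap at full health is available but off by default,
#' because truncating sampled utilities at 1 systematically biases
#' incremental (between-arm) QALY differences towards zero in the
#' probabilistic analysis while leaving the deterministic base case (where
#' the cap never binds at default inputs) untouched.
#'
#' @param age_years age(s) in years.
#' @param ados ADOS severity score.
#' @param iq cognitive ability (must be positive; enters as natural log).
#' @param vabs adaptive-behaviour composite.
#' @param coef named vector/list with elements `u_const`, `u_age`, `u_age2`,
#'   `u_ados`, `u_logiq`, `u_vabs` (defaults: the packaged means).
#' @param cap_at_one cap utilities at 1 (default FALSE).
#' @return utility value(s).
#' @examples
#' utility(3, 6.98, 59.43, 63.19)  # ~0.526 at the default baseline
#' @export
utility <- function(age_years, ados, iq, vabs,
                    coef = param_means(aba_parameters()), cap_at_one = FALSE) {
  if (any(iq <= 0)) stop("utility model requires iq > 0 (log term)")
  coef <- as.list(coef)
  u <- coef$u_const + coef$u_age * age_years + coef$u_age2 * age_years^2 +
    coef$u_ados * ados + coef$u_logiq * log(iq) + coef$u_vabs * vabs
  if (cap_at_one) u <- pmin(u, 1)
  u
}

#' Read a life table
#'
#' CSV with header columns `age` (whole years) and `qx` (annual death
#' probability).
#'
#' @param path CSV path.
#' @return data frame with columns `age`, `qx`.
#' @export
read_life_table <- function(path) {
  lt <- utils::read.csv(path)
  if (!all(c("age", "qx") %in% names(lt))) stop("life table must have columns 'age' and 'qx'")
  if (any(lt$qx < 0 | lt$qx > 1)) stop("life table qx values must lie in [0, 1]")
  lt[order(lt$age), c("age", "qx")]
}

#' Mortality model held in a parameter set
#'
#' Assembles the life table (the configured one, or the packaged synthetic
#' general-population table) and the autism mortality relative risk.
#'
#' @param params an [aba_parameters()] object.
#' @return list with elements `life_table` and `relative_risk`, class
#'   `mortality_model`.
#' @export
default_mortality <- function(params) {
  lt <- params$settings$life_table
  if (is.null(lt)) lt <- make_life_table()
  if (any(lt$qx < 0 | lt$qx > 1)) stop("life table qx values must lie in [0, 1]")
  structure(list(life_table = lt, relative_risk = param_mean(params, "rr_mortality")),
            class = "mortality_model")
}

#' Cohort survival curve
#'
#' Monthly survival fractions from an annual life table with the relative
#' risk applied on the hazard scale: the monthly survival factor at age `a`
#' is `exp(-RR * (-log(1 - qx(a))) / 12)` and survival is the running
#' product (so at RR = 2 and constant `qx`, 12-month survival is
#' `(1 - qx)^2`).  Mortality is identical in both arms.
#'
#' @param model a `mortality_model` (see [default_mortality()]).
#' @param start_age_years cohort age at month 0.
#' @param horizon_months number of months.
#' @return numeric vector of length `horizon_months + 1`, starting at 1,
#'   non-increasing.
#' @export
survival_curve <- function(model, start_age_years, horizon_months) {
  stopifnot(inherits(model, "mortality_model"))
  lt <- model$life_table
  t <- 0:(horizon_months - 1)
  ages <- floor(start_age_years + t / 12)
  idx <- match(ages, lt$age)
  if (anyNA(idx)) stop("life table does not cover ages ", min(ages), "-", max(ages))
  qx <- lt$qx[idx]
  monthly <- exp(-model$relative_risk * (-log(pmax(1e-300, 1 - qx))) / 12)
  monthly[qx >= 1] <- 0
  c(1, cumprod(monthly))
}

#' Total discounted QALYs for a trajectory
#'
#' Per-cycle utility (evaluated at the cycle-start state) times the survival
#' fraction times 1/12 of a year, accumulated with mid-cycle discounting.
#' By default IQ and ADOS enter the utility algorithm at their baseline
#' values (the utility study's predictors) while VABS and age vary;
#' `settings$utility_time_varying_iq = TRUE` lets IQ track the trajectory.
#'
#' @param traj a `cea_trajectory` from [build_trajectory()].
#' @param params an [aba_parameters()] object (utility coefficients and
#'   settings).
#' @return discounted QALY total.
#' @export
total_qalys <- function(traj, params) {
  stopifnot(inherits(traj, "cea_trajectory"), inherits(params, "aba_parameters"))
  s <- params$settings
  m <- param_means(params)
  H <- nrow(traj) - 1L
  i <- seq_len(H)  # cycle-start states 0..H-1
  iq <- if (s$utility_time_varying_iq) traj$iq[i] else rep(m[["iq0"]], H)
  u <- utility(traj$age_months[i] / 12, traj$ados[i], iq, traj$vabs[i],
               coef = m, cap_at_one = s$utility_cap_at_one)
  accumulate(u * traj$survival[i] / 12, s$discount_rate_annual, s$discounting)
}
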