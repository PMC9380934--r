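# Deterministic model runner.  The public module functions (build_trajectory,
# total_qalys, total_costs, ...) expose each step; .eval_model is the
# equivalent vectorised fast path shared by the base case, the one-way
# sensitivity analysis and the Monte Carlo analysis (equivalence is covered
# by tests).

# Precompute everything that does not change with parameter draws.
.model_context <- function(params, scenario = c("base", "placement", "adult")) {
  scenario <- match.arg(scenario)
  s <- params$settings
  Hc <- s$horizon_months
  H <- if (scenario == "adult") as.integer(round((s$max_age_years - s$start_age_years) * 12)) else Hc
  if (H < Hc) stop("max_age_years implies a horizon shorter than childhood")
  dfv <- .cycle_discount(H, s$discount_rate_annual, s$discounting)
  mort <- default_mortality(params)
  surv <- survival_curve(mort, s$start_age_years, H)
  indep <- if (scenario == "adult") .get_independence_model(params) else NULL
  list(s = s, H = H, Hc = Hc, dfv = dfv, surv = surv[seq_len(H)],
       scenario = scenario, indep = indep)
}

# Evaluate both arms for one draw of parameter means `m` (named vector).
# Returns per-arm QALYs and cost categories; NULL if the draw is invalid
# (non-positive IQ path or disordered logit cut-points).
.eval_model <- function(m, ctx, durability) {
  s <- ctx$s; H <- ctx$H; Hc <- ctx$Hc
  t <- seq_len(H) - 1          # cycle starts
  tf <- pmin(t, Hc)            # scores freeze at the end of childhood
  wash <- s$pessimistic_washout_end_months
  if (m[["edu_pri_cut1"]] >= m[["edu_pri_cut2"]] ||
      m[["edu_sec_cut1"]] >= m[["edu_sec_cut2"]]) return(NULL)

  iq_tau <- m[["iq0"]] + m[["d_iq_per_year"]] * tf / 12
  vabs_tau <- m[["vabs0"]] + m[["d_vabs_per_year"]] * tf / 12
  eff <- function(y1, y2) treatment_effect(tf, y1, y2, durability, wash)
  iq_aba <- iq_tau + eff(m[["eff_y1_iq"]], m[["eff_y2_iq"]])
  vabs_aba <- vabs_tau + eff(m[["eff_y1_vabs"]], m[["eff_y2_vabs"]])
  if (min(iq_tau, iq_aba) <= 0) return(NULL)

  child <- t < Hc
  age <- ifelse(child, s$start_age_years + t / 12, 18)
  dec <- ifelse(child, 0,
                s$adult_decrement_per_decade * ((s$start_age_years + t / 12) - 18) / 10)
  uf <- function(iq, vabs) {
    iqu <- if (s$utility_time_varying_iq) iq else m[["iq0"]]
    u <- m[["u_const"]] + m[["u_age"]] * age + m[["u_age2"]] * age^2 +
      m[["u_ados"]] * m[["ados0"]] + m[["u_logiq"]] * log(iqu) +
      m[["u_vabs"]] * vabs - dec
    if (s$utility_cap_at_one) u <- pmin(u, 1)
    u
  }
  dw <- ctx$dfv * ctx$surv
  q_tau <- sum(uf(iq_tau, vabs_tau) / 12 * dw)
  q_aba <- sum(uf(iq_aba, vabs_aba) / 12 * dw)

  # education placement mixes at phase entry (frozen within phase)
  unit_school <- c(m[["school_mainstream"]], m[["school_supported"]], m[["school_special"]])
  mixes <- function(iq, vabs) {
    if (ctx$scenario == "placement") return(NULL)  # handled per arm below
    em <- .edu_models(m)
    i1 <- s$preschool_end_months + 1L; i2 <- s$primary_end_months + 1L
    list(primary = placement_probs(em$primary, iq[i1], vabs[i1]),
         secondary = placement_probs(em$secondary, iq[i2], vabs[i2]))
  }
  obs_mix <- function(arm) {
    pre <- paste0("obs_", arm, "_")
    p <- c(m[[paste0(pre, "mainstream")]], m[[paste0(pre, "supported")]],
           m[[paste0(pre, "special")]])
    p / sum(p)
  }
  school_cost <- function(iq, vabs, arm) {
    flow <- numeric(H)
    in_pri <- t >= s$preschool_end_months & t < s$primary_end_months
    in_sec <- t >= s$primary_end_months & t < Hc
    if (ctx$scenario == "placement") {
      mix <- obs_mix(arm)
      flow[in_pri | in_sec] <- sum(mix * unit_school) / 12
    } else {
      mx <- mixes(iq, vabs)
      flow[in_pri] <- sum(mx$primary * unit_school) / 12
      flow[in_sec] <- sum(mx$secondary * unit_school) / 12
    }
    sum(flow * dw)
  }
  socmed_cost <- function(iq, vabs)
    sum(ifelse(child, pmax(0, m[["socmed_intercept"]] + m[["socmed_vabs"]] * vabs +
                             m[["socmed_iq"]] * iq), 0) / 12 * dw)
  int_cost <- function(arm) {
    win <- if (arm == "aba") s$treatment_duration_months else s$tau_cost_window_months
    ann <- if (arm == "aba") m[["cost_aba_annual"]] else m[["cost_tau_annual"]]
    sum(ifelse(t < win, ann / 12, 0) * dw)
  }
  adult_cost <- function(vabs) {
    if (ctx$scenario != "adult" || H == Hc) return(0)
    mix <- independence_mix(ctx$indep, vabs[Hc + 1L])
    bundles <- vapply(s$adult_bundles, function(items) sum(m[items]), numeric(1))
    annual <- sum(mix * bundles[names(mix)])
    sum(ifelse(child, 0, annual / 12) * dw)
  }

  list(
    tau = list(qalys = q_tau,
               intervention = int_cost("tau"),
               schooling = school_cost(iq_tau, vabs_tau, "tau"),
               social_medical = socmed_cost(iq_tau, vabs_tau),
               adult_care = adult_cost(vabs_tau)),
    aba = list(qalys = q_aba,
               intervention = int_cost("aba"),
               schooling = school_cost(iq_aba, vabs_aba, "aba"),
               social_medical = socmed_cost(iq_aba, vabs_aba),
               adult_care = adult_cost(vabs_aba))
  )
}

.arm_total <- function(x, perspective) {
  base <- x$intervention + x$social_medical + x$adult_care
  if (perspective == "public_sector") base + x$schooling else base
}

#' Run the deterministic cost-effectiveness analysis
#'
#' Full pipeline at parameter means: cohort trajectories, education
#' placement, discounted QALYs and costs, incremental results and ICER.
#'
#' @param params an [aba_parameters()] object (or a config loaded with
#'   [load_parameters()]).
#' @param perspective `"public_sector"` (includes schooling costs) or
#'   `"nhs_social"` (health and social care payer).
#' @param durability long-term treatment-effect assumption, `"pessimistic"`
#'   (linear washout to zero at age 10) or `"optimistic"` (two-year effect
#'   persists).
#' @param scenario `"base"`, `"placement"` (observed education placement
#'   applied throughout childhood) or `"adult"` (lifetime horizon with the
#'   adult-independence phase).
#' @param means optional named vector of parameter means overriding
#'   `param_means(params)` (used by the sensitivity analyses).
#' @return object of class `cea_result`.
#' @examples
#' res <- run_basecase(aba_parameters(), "public_sector", "pessimistic")
#' res
#' @export
run_basecase <- function(params,
                         perspective = c("public_sector", "nhs_social"),
                         durability = c("pessimistic", "optimistic"),
                         scenario = c("base", "placement", "adult"),
                         means = NULL) {
  perspective <- match.arg(perspective)
  durability <- match.arg(durability)
  scenario <- match.arg(scenario)
  params <- validate_parameters(params)
  ctx <- .model_context(params, scenario)
  m <- if (is.null(means)) param_means(params) else means
  ev <- .eval_model(m, ctx, durability)
  if (is.null(ev)) stop("model error: invalid parameter values (IQ path or cut-points)")
  cost_tau <- .arm_total(ev$tau, perspective)
  cost_aba <- .arm_total(ev$aba, perspective)
  inc_cost <- cost_aba - cost_tau
  inc_qaly <- ev$aba$qalys - ev$tau$qalys
  structure(list(
    perspective = perspective, durability = durability, scenario = scenario,
    arms = data.frame(arm = c("ABA", "TAU"),
                      cost = c(cost_aba, cost_tau),
                      qalys = c(ev$aba$qalys, ev$tau$qalys)),
    breakdown = list(ABA = ev$aba, TAU = ev$tau),
    inc_cost = inc_cost, inc_qaly = inc_qaly,
    icer = icer(inc_cost, inc_qaly)
  ), class = "cea_result")
}

#' Incremental cost-effectiveness ratio with dominance flags
#'
#' `inc_cost / inc_qaly` when the incremental QALYs are non-zero and signs
#' do not imply dominance; `"dominant"` (more QALYs, lower cost) and
#' `"dominated"` (fewer QALYs, higher cost) carry no ratio; zero incremental
#' QALYs make the ratio undefined.
#'
#' @param inc_cost incremental cost (intervention minus comparator).
#' @param inc_qaly incremental QALYs.
#' @return list with elements `value` (NA under dominance/undefined) and
#'   `status` (one of `"icer"`, `"dominant"`, `"dominated"`, `"undefined"`).
#' @export
icer <- function(inc_cost, inc_qaly) {
  if (inc_qaly == 0) return(list(value = NA_real_, status = "undefined"))
  if (inc_qaly > 0 && inc_cost < 0) return(list(value = NA_real_, status = "dominant"))
  if (inc_qaly < 0 && inc_cost > 0) return(list(value = NA_real_, status = "dominated"))
  list(value = inc_cost / inc_qaly, status = "icer")
}

#' Additional benefit required to meet a willingness-to-pay threshold
#'
#' For a result with positive incremental costs, the further QALYs
#' (`inc_cost / threshold - inc_qaly`) or further cost savings
#' (`inc_cost - threshold * inc_qaly`) that would bring the ICER down to
#' the threshold.
#'
#' @param result a `cea_result`, or a numeric incremental cost (then
#'   `inc_qaly` must be given).
#' @param threshold willingness-to-pay threshold, GBP/QALY (> 0).
#' @param inc_qaly incremental QALYs when `result` is numeric.
#' @return named vector `c(extra_qalys, extra_savings)`.
#' @export
required_additional_benefit <- function(result, threshold = 30000, inc_qaly = NULL) {
  if (threshold <= 0) stop("threshold must be positive")
  if (inherits(result, "cea_result")) {
    inc_cost <- result$inc_cost; inc_qaly <- result$inc_qaly
  } else {
    inc_cost <- result
    if (is.null(inc_qaly)) stop("inc_qaly must be supplied with a numeric inc_cost")
  }
  if (inc_cost <= 0) stop("required_additional_benefit needs a positive incremental cost")
  c(extra_qalys = inc_cost / threshold - inc_qaly,
    extra_savings = inc_cost - threshold * inc_qaly)
}

.fmt_gbp <- function(x) ifelse(is.na(x), "-", paste0("£", formatC(x, format = "f", digits = 0, big.mark = ",")))

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("Cost-effectiveness result (%s scenario, %s durability, %s perspective)\n",
              x$scenario, x$durability,
              ifelse(x$perspective == "public_sector", "public sector", "NHS & social services")))
  tab <- x$arms
  cat(sprintf("  %-4s cost %12s   QALYs %6.2f\n", tab$arm[1], .fmt_gbp(tab$cost[1]), tab$qalys[1]))
  cat(sprintf("  %-4s cost %12s   QALYs %6.2f\n", tab$arm[2], .fmt_gbp(tab$cost[2]), tab$qalys[2]))
  cat(sprintf("  incremental cost %s, incremental QALYs %.4f\n",
              .fmt_gbp(x$inc_cost), x$inc_qaly))
  if (x$icer$status == "icer") {
    cat(sprintf("  ICER %s per QALY\n", .fmt_gbp(x$icer$value)))
  } else cat(sprintf("  ICER: %s\n", x$icer$status))
  invisible(x)
}

#' @export
summary.cea_result <- function(object, thresholds = c(20000, 30000), ...) {
  print(object)
  cat("  cost breakdown (discounted):\n")
  for (arm in c("ABA", "TAU")) {
    b <- object$breakdown[[arm]]
    cat(sprintf("    %-4s intervention %s, schooling %s, social/medical %s, adult care %s\n",
                arm, .fmt_gbp(b$intervention), .fmt_gbp(b$schooling),
                .fmt_gbp(b$social_medical), .fmt_gbp(b$adult_care)))
  }
  if (object$icer$status == "icer" && object$inc_cost > 0) {
    for (th in thresholds) {
      rab <- required_additional_benefit(object, th)
      cat(sprintf("  at £%s/QALY: %.2f further QALYs or %s further savings needed\n",
                  formatC(th, format = "d", big.mark = ","),
                  max(0, rab["extra_qalys"]), .fmt_gbp(max(0, rab["extra_savings"]))))
    }
  }
  invisible(object)
}
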