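# Model parameterisation: every input of the economic analysis carried as a
# (mean, SE, distribution, bounds) row, plus structural settings.  The row
# table is the single source used by the deterministic engine (means), the
# one-way sensitivity analysis (bounds) and the probabilistic analysis
# (distribution families).

# distribution families actually sampled:
#   normal  - unbounded regression coefficients / score changes
#   gamma   - positive cost parameters, moment-matched
#   tnorm   - continuous scores and coefficients reported with a
#             "beta-binomial"-style bounded distribution: truncated normal
#             on [lower, upper] (a beta-binomial is undefined for these)
#   beta    - proportions in [0, 1], moment-matched
#   fixed   - se = 0, never varied
.PARAM_FAMILIES <- c("normal", "gamma", "tnorm", "beta", "fixed")

.default_param_table <- function() {
  # name, block, mean, se, dist, lower, upper, units
  rows <- list(
    # Baseline cohort characteristics (age 3 years at model start)
    list("prop_male",                   "baseline", 0.8757, 0.0147, "beta",  0.8469, 0.9045, "proportion"),
    # printed bounds for this row duplicate the IQ row; recomputed as mean +/- 1.96 SE
    list("prop_intellectual_disability","baseline", 0.8295, 0.0332, "beta",  0.7644, 0.8946, "proportion"),
    list("age_months",                  "baseline", 36,      0,     "fixed", NA,     NA,     "months"),
    list("vabs0",                       "baseline", 63.19,  0.43,   "tnorm", 62.35,  64.04,  "VABS composite"),
    list("iq0",                         "baseline", 59.43,  1.08,   "tnorm", 57.32,  61.55,  "ratio IQ"),
    list("ados0",                       "baseline", 6.98,   0.18,   "tnorm", 6.63,   7.33,   "ADOS severity"),
    # Natural history: annual drift of cohort mean scores under TAU
    list("d_vabs_per_year", "natural_history", -0.45, 1.27, "normal", -2.94, 2.04, "VABS points/year"),
    list("d_iq_per_year",   "natural_history", -0.28, 1.24, "normal", -2.70, 2.14, "IQ points/year"),
    # Short-term treatment effect (ABA minus TAU) at one and two years
    list("eff_y1_vabs", "effect_y1", 2.92, 2.46, "normal", -1.90, 7.76,  "VABS points"),
    list("eff_y1_iq",   "effect_y1", 9.16, 2.44, "normal",  4.38, 13.93, "IQ points"),
    list("eff_y2_vabs", "effect_y2", 7.00, 2.58, "normal",  1.95, 12.06, "VABS points"),
    list("eff_y2_iq",   "effect_y2", 14.13, 2.54, "normal", 9.16, 19.10, "IQ points"),
    # Ordered-logit education placement, primary entry.  The printed SE of
    # cut 1 (0.02) is inconsistent with its own 95% bounds; SE taken as
    # (upper - lower)/3.92.
    list("edu_pri_vabs", "education_primary", -0.08, 0.02, "normal", -0.120, -0.042, "per VABS point"),
    list("edu_pri_iq",   "education_primary", -0.02, 0.01, "normal", -0.051,  0.006, "per IQ point"),
    list("edu_pri_cut1", "education_primary", -8.75, 1.19, "normal", -11.08, -6.42,  "logit"),
    list("edu_pri_cut2", "education_primary", -6.10, 0.86, "normal", -7.781, -4.41,  "logit"),
    # Ordered-logit education placement, secondary entry.  The printed
    # lower/upper columns of this block are cyclically shifted by two rows
    # (each coefficient's mean +/- 1.96 SE reproduces the bounds printed two
    # rows away); they are re-attached to the correct rows here.
    list("edu_sec_vabs", "education_secondary", -0.04, 0.02, "normal", -0.084, -0.001, "per VABS point"),
    list("edu_sec_iq",   "education_secondary", -0.06, 0.02, "normal", -0.089, -0.025, "per IQ point"),
    list("edu_sec_cut1", "education_secondary", -9.37, 1.58, "normal", -12.48, -6.27,  "logit"),
    list("edu_sec_cut2", "education_secondary", -6.60, 1.39, "normal", -9.32,  -3.89,  "logit"),
    # Observed education placement (scenario analysis only)
    list("obs_aba_mainstream", "placement_observed", 0.30, 0, "fixed", NA, NA, "proportion"),
    list("obs_aba_supported",  "placement_observed", 0.38, 0, "fixed", NA, NA, "proportion"),
    list("obs_aba_special",    "placement_observed", 0.32, 0, "fixed", NA, NA, "proportion"),
    list("obs_tau_mainstream", "placement_observed", 0.01, 0, "fixed", NA, NA, "proportion"),
    list("obs_tau_supported",  "placement_observed", 0.27, 0, "fixed", NA, NA, "proportion"),
    list("obs_tau_special",    "placement_observed", 0.72, 0, "fixed", NA, NA, "proportion"),
    # Utility regression for children (EQ-5D scale).  The printed ADOS and
    # VABS bounds are swapped relative to their means/SEs; re-swapped here.
    list("u_const", "utility", -0.2438, 0.2015, "tnorm", -0.639,  0.154,  "utility"),
    list("u_age",   "utility",  0.0119, 0.0186, "tnorm", -0.025,  0.048,  "per year of age"),
    list("u_age2",  "utility",  0.0003, 0.0010, "tnorm", -0.002,  0.001,  "per year^2"),
    list("u_ados",  "utility", -0.0063, 0.0078, "tnorm", -0.021,  0.009,  "per ADOS point"),
    list("u_logiq", "utility",  0.0304, 0.0478, "tnorm", -0.063,  0.124,  "per log(IQ)"),
    list("u_vabs",  "utility",  0.0103, 0.0016, "tnorm",  0.0071, 0.013,  "per VABS point"),
    # Intervention costs, per annum, GBP 2016/17
    list("cost_aba_annual", "costs", 36682.78, 7336, "gamma", 22303, 51062, "GBP/year"),
    list("cost_tau_annual", "costs", 8634.33,  1726, "gamma", 5249,  12019, "GBP/year"),
    # Social care + medical cost regression (annual, GBP)
    list("socmed_intercept", "costs", 1900.09, 762.41, "normal", 405,    3394,  "GBP/year"),
    list("socmed_vabs",      "costs", -8.78,   13.98,  "normal", -36.18, 18.63, "GBP/VABS point"),
    list("socmed_iq",        "costs", -7.81,   10.99,  "normal", -29.35, 13.74, "GBP/IQ point"),
    # Schooling costs, per annum
    list("school_mainstream", "costs", 4417.70,  883,  "gamma", 2686, 6149,  "GBP/year"),
    list("school_supported",  "costs", 8689.78,  1737, "gamma", 5283, 12096, "GBP/year"),
    list("school_special",    "costs", 15702.78, 3140, "gamma", 9547, 21858, "GBP/year"),
    # Adult care unit costs, per annum (lifetime scenario only)
    list("adult_own_home",       "adult_costs", 0,         0,        "fixed", NA,    NA,     "GBP/year"),
    list("adult_sheltered_low",  "adult_costs", 53274.88,  10654.98, "gamma", 32391, 74159,  "GBP/year"),
    list("adult_sheltered_high", "adult_costs", 99336.44,  19867.29, "gamma", 60397, 138276, "GBP/year"),
    list("adult_residential",    "adult_costs", 115553.00, 23110.60, "gamma", 70256, 160850, "GBP/year"),
    list("adult_day_services",   "adult_costs", 17728.57,  3545.71,  "gamma", 10779, 24678,  "GBP/year"),
    list("adult_respite",        "adult_costs", 1927.00,   385.40,   "gamma", 1172,  2682,   "GBP/year"),
    list("adult_employment",     "adult_costs", 290.00,    58.00,    "gamma", 176,   404,    "GBP/year"),
    list("adult_education",      "adult_costs", 4159.00,   831.80,   "gamma", 2529,  5789.328, "GBP/year"),
    list("adult_hospital",       "adult_costs", 43.00,     8.60,     "gamma", 26.14, 59.86,  "GBP/year"),
    list("adult_other",          "adult_costs", 726.00,    145.20,   "gamma", 441,   1010,   "GBP/year"),
    # Autism mortality relative risk: not a published input of this analysis;
    # placeholder consistent with registry-based estimates, fixed by default.
    list("rr_mortality", "mortality", 2.56, 0, "fixed", NA, NA, "rate ratio")
  )
  tab <- do.call(rbind, lapply(rows, function(r) {
    data.frame(name = r[[1]], block = r[[2]], mean = r[[3]], se = r[[4]],
               dist = r[[5]], lower = r[[6]], upper = r[[7]], units = r[[8]],
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- tab$name
  tab
}

.default_settings <- function() {
  list(
    horizon_months = 186L,           # age 3 to 18.5 years
    cycle_length_months = 1L,
    discount_rate_annual = 0.035,
    discounting = "monthly",         # or "annual": step discounting by model year
    treatment_duration_months = 24L,
    tau_cost_window_months = 24L,    # nursery-provision costing window for TAU
    preschool_end_months = 18L,      # age 4.5 y: primary-school entry
    primary_end_months = 102L,       # age 11.5 y: secondary-school entry
    pessimistic_washout_end_months = 84L,  # age 10 y: treatment effect fully dissipated
    utility_time_varying_iq = FALSE, # IQ (and ADOS) enter the utility model at baseline values
    utility_cap_at_one = FALSE,      # cap biases incremental QALYs under sampling; see vignette
    start_age_years = 3,
    max_age_years = 80,              # lifetime-scenario horizon
    adult_decrement_per_decade = 0,  # additive utility decrement per decade past 18
    wtp_grid = seq(0, 200000, by = 1000),
    psa_iterations = 10000L,
    psa_redraw_limit = 100L,
    life_table = NULL,               # data.frame(age, qx); NULL -> synthetic default
    adult = list(                    # simulated-IPD generator + fitted-model slot
      level_means = c(85, 70, 57.5, 45, 30),  # VABS by independence level, most to least independent
      level_sd = 8,
      level_prev = c(0.17, 0.20, 0.23, 0.20, 0.20),
      n_ipd = 5000L,
      ipd_seed = 1234L,
      coefficients = NULL            # list(beta_vabs=, cuts=) to inject a known model
    ),
    adult_bundles = list(            # unit-cost names composing each level's annual bundle
      completely_independent = character(0),
      mostly_independent = c("adult_employment", "adult_education", "adult_hospital", "adult_other"),
      some_independence = c("adult_sheltered_low", "adult_respite", "adult_employment",
                            "adult_education", "adult_hospital", "adult_other"),
      mostly_dependent = c("adult_sheltered_high", "adult_day_services", "adult_respite",
                           "adult_hospital", "adult_other"),
      completely_dependent = c("adult_residential", "adult_day_services", "adult_respite",
                               "adult_hospital", "adult_other")
    )
  )
}

#' Default model parameterisation
#'
#' Builds the complete default parameter set of the economic analysis: every
#' input carried with its mean, standard error, sampling distribution and
#' 95% bounds, plus the structural settings (horizon, cycle length, discount
#' rate, phase boundaries, scenario switches).
#'
#' Monetary values are GBP at 2016/17 prices.  Distribution families are
#' resolved from the reported ones: bounded continuous quantities are
#' truncated normals, cost parameters are moment-matched gammas, proportions
#' are moment-matched betas, and regression coefficients are normals.  A few
#' bound/SE columns of the source table are internally inconsistent (they do
#' not bracket their own means); these are reconciled deterministically as
#' described in the package vignette.
#'
#' @param settings optional list of settings overriding the defaults (only
#'   the named elements given are replaced).
#' @return An object of class `aba_parameters`: a list with elements `tbl`
#'   (the parameter data frame) and `settings`.
#' @examples
#' p <- aba_parameters()
#' param_mean(p, "iq0")
#' @export
aba_parameters <- function(settings = list()) {
  s <- utils::modifyList(.default_settings(), settings)
  p <- structure(list(tbl = .default_param_table(), settings = s),
                 class = "aba_parameters")
  validate_parameters(p)
}

#' Validate a parameter set
#'
#' Checks every parameter row (SE non-negative, `se = 0` iff the family is
#' `fixed`, bounds bracket the mean, gamma means positive, proportions in
#' \[0, 1\]) and the structural settings (phase ordering, positive treatment
#' duration, observed placement mixes summing to one).  Observed placement
#' proportions are renormalised if they sum to 1 within 1e-6 but not
#' exactly.
#'
#' @param p an `aba_parameters` object.
#' @return `p`, invisibly modified (normalised proportions), or an error
#'   naming the offending field.
#' @export
validate_parameters <- function(p) {
  stopifnot(inherits(p, "aba_parameters"))
  tab <- p$tbl
  if (anyDuplicated(tab$name)) stop("duplicated parameter names")
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    if (!r$dist %in% .PARAM_FAMILIES)
      stop(sprintf("parameter '%s': unknown distribution family '%s'", r$name, r$dist))
    if (is.na(r$mean)) stop(sprintf("parameter '%s': mean is missing", r$name))
    if (is.na(r$se) || r$se < 0) stop(sprintf("parameter '%s': se must be >= 0", r$name))
    if ((r$se == 0) != (r$dist == "fixed"))
      stop(sprintf("parameter '%s': se = 0 if and only if dist = 'fixed'", r$name))
    if (!is.na(r$lower) && !is.na(r$upper)) {
      if (r$lower > r$upper)
        stop(sprintf("parameter '%s': lower bound exceeds upper bound", r$name))
      if (r$mean < r$lower || r$mean > r$upper)
        stop(sprintf("parameter '%s': mean outside [lower, upper]", r$name))
    }
    if (r$dist == "gamma" && (r$mean <= 0))
      stop(sprintf("parameter '%s': gamma-distributed mean must be positive", r$name))
    if (r$dist == "beta" && (r$mean < 0 || r$mean > 1))
      stop(sprintf("parameter '%s': beta-distributed mean must lie in [0, 1]", r$name))
  }
  for (arm in c("aba", "tau")) {
    nm <- paste0("obs_", arm, "_", c("mainstream", "supported", "special"))
    tot <- sum(tab[nm, "mean"])
    if (abs(tot - 1) > 1e-6)
      stop(sprintf("observed placement proportions for %s sum to %.6f, not 1", toupper(arm), tot))
    p$tbl[nm, "mean"] <- tab[nm, "mean"] / tot
  }
  s <- p$settings
  if (!(s$treatment_duration_months > 0 && s$treatment_duration_months <= s$horizon_months))
    stop("settings: treatment_duration_months must lie in (0, horizon_months]")
  if (!(s$preschool_end_months < s$primary_end_months && s$primary_end_months < s$horizon_months))
    stop("settings: require preschool_end < primary_end < horizon")
  if (s$pessimistic_washout_end_months <= s$treatment_duration_months)
    stop("settings: pessimistic washout must end after treatment ends")
  if (!s$discounting %in% c("monthly", "annual"))
    stop("settings: discounting must be 'monthly' or 'annual'")
  invisible(p)
}

# restore native R types that a YAML/JSON round trip flattens
.sanitise_settings <- function(s) {
  num <- function(x) if (is.null(x)) NULL else as.numeric(unlist(x))
  s$wtp_grid <- num(s$wtp_grid)
  if (!is.null(s$life_table) && !is.data.frame(s$life_table))
    s$life_table <- as.data.frame(lapply(s$life_table, unlist))
  s$adult_bundles <- lapply(s$adult_bundles, function(b) as.character(unlist(b)))
  for (f in c("level_means", "level_prev")) s$adult[[f]] <- num(s$adult[[f]])
  if (!is.null(s$adult$coefficients)) {
    s$adult$coefficients <- list(beta_vabs = as.numeric(s$adult$coefficients$beta_vabs),
                                 cuts = num(s$adult$coefficients$cuts))
  } else if (!("coefficients" %in% names(s$adult))) {
    s$adult["coefficients"] <- list(NULL)  # modifyList drops explicit nulls
  }
  int_fields <- c("horizon_months", "cycle_length_months", "treatment_duration_months",
                  "tau_cost_window_months", "preschool_end_months", "primary_end_months",
                  "pessimistic_washout_end_months", "psa_iterations", "psa_redraw_limit",
                  "n_ipd")
  for (f in intersect(int_fields, names(s))) s[[f]] <- as.integer(s[[f]])
  s$adult$n_ipd <- as.integer(s$adult$n_ipd)
  s$adult$ipd_seed <- as.integer(s$adult$ipd_seed)
  s
}

#' Read a parameter configuration file
#'
#' Reads a YAML or JSON configuration (extension-dispatched) and merges it
#' onto the packaged defaults: any parameter row or setting not given keeps
#' its default value.  Parameter entries are maps keyed by parameter name
#' with any of `mean`, `se`, `dist`, `lower`, `upper`; settings go under a
#' `settings` key.  The result is validated before being returned.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a validated `aba_parameters` object.
#' @seealso [write_parameters()], [aba_parameters()]
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config must be a .yaml/.yml or .json file: ", path)
  p <- aba_parameters()
  if (!is.null(cfg$settings)) {
    known <- names(.default_settings())
    bad <- setdiff(names(cfg$settings), known)
    if (length(bad)) stop("unknown settings: ", paste(bad, collapse = ", "))
    given <- cfg$settings[!vapply(cfg$settings, is.null, logical(1))]
    p$settings <- utils::modifyList(p$settings, given)
    p$settings <- .sanitise_settings(p$settings)
  }
  if (!is.null(cfg$parameters)) {
    for (nm in names(cfg$parameters)) {
      if (!nm %in% rownames(p$tbl))
        stop("unknown parameter in config: '", nm, "'")
      entry <- cfg$parameters[[nm]]
      bad <- setdiff(names(entry), c("mean", "se", "dist", "lower", "upper", "units"))
      if (length(bad))
        stop(sprintf("parameter '%s': unknown field(s) %s", nm, paste(bad, collapse = ", ")))
      for (f in names(entry))
        if (!is.null(entry[[f]]) && length(entry[[f]]) == 1) p$tbl[nm, f] <- entry[[f]]
    }
  }
  validate_parameters(p)
}

#' Serialise a parameter set to YAML or JSON
#'
#' Writes the full parameter table and settings in the schema read by
#' [load_parameters()]; a load of the written file reproduces the object.
#'
#' @param p an `aba_parameters` object.
#' @param path output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(p, path) {
  stopifnot(inherits(p, "aba_parameters"))
  pars <- lapply(seq_len(nrow(p$tbl)), function(i) {
    r <- p$tbl[i, ]
    list(mean = r$mean, se = r$se, dist = r$dist,
         lower = if (is.na(r$lower)) NULL else r$lower,
         upper = if (is.na(r$upper)) NULL else r$upper,
         units = r$units)
  })
  names(pars) <- p$tbl$name
  s <- p$settings
  cfg <- list(parameters = pars, settings = s)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(cfg, path, precision = 15)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else stop("path must end in .yaml/.yml or .json")
  invisible(path)
}

#' @export
print.aba_parameters <- function(x, ...) {
  cat("Model parameter set:", nrow(x$tbl), "parameters in",
      length(unique(x$tbl$block)), "blocks\n")
  cat(sprintf("  horizon %d months, cycle %d month, discount %.1f%% (%s)\n",
              x$settings$horizon_months, x$settings$cycle_length_months,
              100 * x$settings$discount_rate_annual, x$settings$discounting))
  n_var <- sum(x$tbl$dist != "fixed")
  cat(sprintf("  %d parameters carry sampling distributions (%s)\n", n_var,
              paste(names(table(x$tbl$dist[x$tbl$dist != "fixed"])), collapse = "/")))
  invisible(x)
}

#' Look up parameter means by name
#'
#' @param p an `aba_parameters` object.
#' @param name parameter name (see `param_table(p)$name`).
#' @return the mean value.
#' @export
param_mean <- function(p, name) {
  stopifnot(inherits(p, "aba_parameters"))
  if (!name %in% rownames(p$tbl)) stop("unknown parameter: '", name, "'")
  p$tbl[name, "mean"]
}

#' Named vector of all parameter means
#' @param p an `aba_parameters` object.
#' @return named numeric vector, one element per parameter.
#' @export
param_means <- function(p) {
  stats::setNames(p$tbl$mean, p$tbl$name)
}

#' The full parameter table
#' @param p an `aba_parameters` object.
#' @return data frame with columns name, block, mean, se, dist, lower,
#'   upper, units.
#' @export
param_table <- function(p) {
  stopifnot(inherits(p, "aba_parameters"))
  tab <- p$tbl
  rownames(tab) <- NULL
  tab
}

#' Modify one parameter row
#'
#' @param p an `aba_parameters` object.
#' @param name parameter name.
#' @param ... any of `mean`, `se`, `dist`, `lower`, `upper` to replace.
#' @return the modified, re-validated parameter set.
#' @export
set_parameter <- function(p, name, ...) {
  stopifnot(inherits(p, "aba_parameters"))
  if (!name %in% rownames(p$tbl)) stop("unknown parameter: '", name, "'")
  fields <- list(...)
  bad <- setdiff(names(fields), c("mean", "se", "dist", "lower", "upper"))
  if (length(bad)) stop("unknown field(s): ", paste(bad, collapse = ", "))
  for (f in names(fields)) p$tbl[name, f] <- fields[[f]]
  validate_parameters(p)
}

#' Gamma distribution parameters from a mean and standard error
#'
#' Method-of-moments parameterisation used for cost parameters:
#' `shape = (mean/se)^2`, `scale = se^2/mean`, so the resulting gamma has
#' exactly the requested mean and SE.
#'
#' @param mean positive mean.
#' @param se positive standard error.
#' @return named numeric vector `c(shape, scale)`.
#' @examples
#' gamma_moments(36682.78, 7336)
#' @export
gamma_moments <- function(mean, se) {
  if (!is.finite(mean) || !is.finite(se) || mean <= 0 || se <= 0)
    stop("gamma_moments requires mean > 0 and se > 0")
  c(shape = (mean / se)^2, scale = se^2 / mean)
}

#' Beta distribution parameters from a mean and standard error
#'
#' Moment-matched beta for proportions: requires `se^2 < mean (1 - mean)`.
#'
#' @param mean mean in (0, 1).
#' @param se positive standard error.
#' @return named numeric vector `c(shape1, shape2)`.
#' @export
beta_moments <- function(mean, se) {
  if (mean <= 0 || mean >= 1 || se <= 0) stop("beta_moments requires mean in (0,1), se > 0")
  v <- se^2
  if (v >= mean * (1 - mean)) stop("se too large for a beta with this mean")
  k <- mean * (1 - mean) / v - 1
  c(shape1 = mean * k, shape2 = (1 - mean) * k)
}
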