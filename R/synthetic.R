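# Synthetic inputs: a general-population life table (the analysis cannot
# ship national statistics), simulated adult individual-level records with
# known ordered structure, and jittered parameter fixtures for testing.

#' Synthetic general-population life table
#'
#' Gompertz-Makeham annual death probabilities,
#' `qx(age) = makeham + a * exp(b * age)`, capped at 1.  The defaults give
#' negligible childhood mortality (cumulative < 0.5% over the 15.5-year
#' childhood horizon) and realistic old-age mortality, standing in for a
#' national life table.
#'
#' @param ages integer ages covered (default 0:110).
#' @param makeham age-independent hazard component (>= 0).
#' @param gompertz_a,gompertz_b exponential component parameters (> 0
#'   and > 0).
#' @return data frame with columns `age`, `qx` (synthetic).
#' @export
make_life_table <- function(ages = 0:110, makeham = 5e-5,
                            gompertz_a = 2e-5, gompertz_b = 0.1) {
  stopifnot(makeham >= 0, gompertz_a >= 0, gompertz_b > 0)
  qx <- pmin(1, makeham + gompertz_a * exp(gompertz_b * ages))
  data.frame(age = as.integer(ages), qx = qx)
}

#' Simulate adult independence-level records
#'
#' Individual records (VABS score, independence level) generated from
#' per-level VABS summaries: each record's level is drawn by prevalence and
#' its VABS from a normal around the level mean (common SD), truncated to
#' \[20, 140\].  This emulates reconstructing individual-level data from
#' published per-level summary statistics so that an ordered logit can be
#' fitted to it.
#'
#' @param n number of records.
#' @param level_means VABS means for the five levels, most independent
#'   first (`completely_independent` down to `completely_dependent`).
#' @param level_sd common within-level SD.
#' @param level_prev level prevalences (most independent first; must sum
#'   to 1).
#' @param seed RNG seed (reproducible).
#' @return data frame with columns `vabs`, `level` (factor, ascending
#'   independence order as used by [fit_independence_model()]).
#' @export
simulate_adult_ipd <- function(n = 5000, level_means = c(85, 70, 57.5, 45, 30),
                               level_sd = 8,
                               level_prev = c(0.17, 0.20, 0.23, 0.20, 0.20),
                               seed = 1L) {
  stopifnot(n >= 1, length(level_means) == 5, length(level_prev) == 5,
            abs(sum(level_prev) - 1) < 1e-9, level_sd >= 0)
  set.seed(seed)
  # inputs are ordered most->least independent; storage order is ascending
  lev_desc <- rev(.INDEP_LEVELS)
  k <- sample.int(5, n, replace = TRUE, prob = level_prev)
  vabs <- stats::rnorm(n, level_means[k], level_sd)
  vabs <- pmin(140, pmax(20, vabs))
  data.frame(vabs = vabs,
             level = factor(lev_desc[k], levels = .INDEP_LEVELS))
}

#' Jittered parameter fixture
#'
#' Perturbs every non-fixed parameter mean by `perturbation * se * z` with
#' independent standard-normal `z`, clamped to the parameter's bounds (and
#' to positivity for gamma-distributed costs), so the result still
#' validates.  `perturbation = 0` returns the input unchanged.  Used for
#' property-style tests over the neighbourhood of the default inputs.
#'
#' @param params an [aba_parameters()] object.
#' @param perturbation jitter scale in SE units (>= 0).
#' @param seed RNG seed.
#' @return a validated `aba_parameters` object.
#' @export
make_fixture <- function(params, perturbation = 0.5, seed = 1L) {
  stopifnot(inherits(params, "aba_parameters"), perturbation >= 0)
  if (perturbation == 0) return(params)
  set.seed(seed)
  tab <- params$tbl
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    if (r$dist == "fixed") next
    x <- r$mean + perturbation * r$se * stats::rnorm(1)
    if (!is.na(r$lower)) x <- max(x, r$lower)
    if (!is.na(r$upper)) x <- min(x, r$upper)
    if (r$dist == "gamma") x <- max(x, r$mean * 1e-3)
    if (r$dist == "beta") x <- min(max(x, 1e-6), 1 - 1e-6)
    tab[i, "mean"] <- x
  }
  params$tbl <- tab
  validate_parameters(params)
}

#' Write a life table to CSV
#'
#' Plain `age,qx` CSV readable by [read_life_table()].
#'
#' @param life_table data frame with columns `age`, `qx`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(life_table, path) {
  utils::write.csv(life_table[, c("age", "qx")], path, row.names = FALSE)
  invisible(path)
}
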