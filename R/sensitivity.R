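# Deterministic (tornado) and probabilistic sensitivity analysis, and the
# cost-effectiveness acceptability curve.

#' One-way deterministic sensitivity analysis
#'
#' For every non-fixed parameter with bounds, the full deterministic model
#' is run with that parameter at its lower and at its upper bound while all
#' others stay at their means; rows are ranked by the absolute ICER range.
#' Time horizon and discount rate are structural settings, not parameters,
#' and are never varied.
#'
#' @param params an [aba_parameters()] object.
#' @param perspective,durability,scenario as in [run_basecase()].
#' @return object of class `cea_dsa`: a data frame with columns
#'   `parameter`, `lower`, `upper`, `icer_at_lower`, `icer_at_upper`,
#'   `range`, sorted by decreasing range, plus attribute `base_icer`.
#' @export
run_dsa <- function(params, perspective = c("public_sector", "nhs_social"),
                    durability = c("pessimistic", "optimistic"),
                    scenario = c("base", "placement", "adult")) {
  perspective <- match.arg(perspective); durability <- match.arg(durability)
  scenario <- match.arg(scenario)
  params <- validate_parameters(params)
  ctx <- .model_context(params, scenario)
  m0 <- param_means(params)
  run_at <- function(m) {
    ev <- .eval_model(m, ctx, durability)
    if (is.null(ev)) return(NA_real_)
    ic <- icer(.arm_total(ev$aba, perspective) - .arm_total(ev$tau, perspective),
               ev$aba$qalys - ev$tau$qalys)
    ic$value
  }
  tab <- params$tbl
  vary <- tab[tab$dist != "fixed" & !is.na(tab$lower) & !is.na(tab$upper), ]
  rows <- lapply(seq_len(nrow(vary)), function(i) {
    nm <- vary$name[i]
    lo <- m0; lo[nm] <- vary$lower[i]
    hi <- m0; hi[nm] <- vary$upper[i]
    il <- run_at(lo); iu <- run_at(hi)
    data.frame(parameter = nm, lower = vary$lower[i], upper = vary$upper[i],
               icer_at_lower = il, icer_at_upper = iu, range = abs(iu - il))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$range, out$parameter, na.last = TRUE), ]
  rownames(out) <- NULL
  structure(out, base_icer = run_at(m0), perspective = perspective,
            durability = durability, scenario = scenario,
            class = c("cea_dsa", "data.frame"))
}

#' @export
print.cea_dsa <- function(x, n = 10, ...) {
  cat(sprintf("One-way sensitivity analysis (%s, %s): base ICER %s/QALY\n",
              attr(x, "perspective"), attr(x, "durability"), .fmt_gbp(attr(x, "base_icer"))))
  top <- utils::head(as.data.frame(x), n)
  top$icer_at_lower <- .fmt_gbp(top$icer_at_lower)
  top$icer_at_upper <- .fmt_gbp(top$icer_at_upper)
  top$range <- .fmt_gbp(top$range)
  print(top[, c("parameter", "icer_at_lower", "icer_at_upper", "range")], row.names = FALSE)
  invisible(x)
}

#' Tornado diagram
#'
#' Horizontal bars spanning the ICER at each parameter's lower and upper
#' bound, for the `n` most influential parameters.
#'
#' @param x a `cea_dsa` object.
#' @param n number of parameters to draw (default 10).
#' @param ... further arguments ignored.
#' @export
plot.cea_dsa <- function(x, n = 10, ...) {
  top <- utils::head(as.data.frame(x)[is.finite(x$range), ], n)
  top <- top[rev(seq_len(nrow(top))), ]
  base <- attr(x, "base_icer")
  rng <- range(c(top$icer_at_lower, top$icer_at_upper, base), finite = TRUE)
  op <- graphics::par(mar = c(5, 11, 3, 2)); on.exit(graphics::par(op))
  graphics::plot(NULL, xlim = rng, ylim = c(0.5, nrow(top) + 0.5), yaxt = "n",
                 xlab = "ICER (GBP/QALY)", ylab = "",
                 main = sprintf("Tornado (%s durability)", attr(x, "durability")))
  graphics::axis(2, at = seq_len(nrow(top)), labels = top$parameter, las = 1, cex.axis = 0.8)
  for (i in seq_len(nrow(top)))
    graphics::rect(min(top$icer_at_lower[i], top$icer_at_upper[i]), i - 0.35,
                   max(top$icer_at_lower[i], top$icer_at_upper[i]), i + 0.35,
                   col = "steelblue", border = NA)
  graphics::abline(v = base, lty = 2)
  invisible(x)
}

# one matrix of parameter draws (n x p); fixed parameters stay at their mean
.sample_parameter_matrix <- function(params, n) {
  tab <- params$tbl
  draws <- matrix(rep(tab$mean, each = n), nrow = n,
                  dimnames = list(NULL, tab$name))
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    if (r$dist == "fixed") next
    draws[, r$name] <- switch(r$dist,
      normal = stats::rnorm(n, r$mean, r$se),
      gamma = { g <- gamma_moments(r$mean, r$se)
                stats::rgamma(n, shape = g["shape"], scale = g["scale"]) },
      tnorm = { pl <- stats::pnorm(r$lower, r$mean, r$se)
                pu <- stats::pnorm(r$upper, r$mean, r$se)
                stats::qnorm(pl + stats::runif(n) * (pu - pl), r$mean, r$se) },
      beta = { b <- beta_moments(r$mean, r$se)
               stats::rbeta(n, b["shape1"], b["shape2"]) })
  }
  draws
}

#' Probabilistic sensitivity analysis
#'
#' Simple Monte Carlo: each iteration draws every non-fixed parameter
#' independently from its distribution (normal, moment-matched gamma,
#' truncated normal, or moment-matched beta per the parameter table) and
#' evaluates the full deterministic model.  Draws producing an invalid
#' model (non-positive IQ anywhere on a trajectory, or disordered
#' placement cut-points) are redrawn, up to
#' `settings$psa_redraw_limit` times each.  The summary ICER is the ratio
#' of mean incrementals (never the mean of per-iteration ratios, which is
#' unstable under sign changes).
#'
#' @param params an [aba_parameters()] object.
#' @param perspective,durability,scenario as in [run_basecase()].
#' @param n iterations (default `settings$psa_iterations`).
#' @param seed RNG seed; the output is reproducible given the seed.
#' @return object of class `cea_psa`: list with `iterations` (data frame
#'   `cost_aba, qaly_aba, cost_tau, qaly_tau`), `summary`, `icer_of_means`,
#'   `n_redraws`, `seed` and the run labels.
#' @export
run_psa <- function(params, perspective = c("public_sector", "nhs_social"),
                    durability = c("pessimistic", "optimistic"),
                    scenario = c("base", "placement", "adult"),
                    n = NULL, seed = 1L) {
  perspective <- match.arg(perspective); durability <- match.arg(durability)
  scenario <- match.arg(scenario)
  params <- validate_parameters(params)
  if (is.null(n)) n <- params$settings$psa_iterations
  stopifnot(n >= 1)
  ctx <- .model_context(params, scenario)
  set.seed(seed)
  draws <- .sample_parameter_matrix(params, n)
  out <- matrix(NA_real_, n, 4, dimnames = list(NULL, c("cost_aba", "qaly_aba", "cost_tau", "qaly_tau")))
  n_redraws <- 0L
  limit <- params$settings$psa_redraw_limit
  for (i in seq_len(n)) {
    m <- draws[i, ]
    ev <- .eval_model(m, ctx, durability)
    tries <- 0L
    while (is.null(ev)) {
      tries <- tries + 1L
      if (tries > limit) stop("PSA: redraw limit reached at iteration ", i)
      m <- .sample_parameter_matrix(params, 1L)[1L, ]
      ev <- .eval_model(m, ctx, durability)
    }
    n_redraws <- n_redraws + tries
    out[i, ] <- c(.arm_total(ev$aba, perspective), ev$aba$qalys,
                  .arm_total(ev$tau, perspective), ev$tau$qalys)
  }
  it <- as.data.frame(out)
  sm <- colMeans(out)
  inc_cost <- sm[["cost_aba"]] - sm[["cost_tau"]]
  inc_qaly <- sm[["qaly_aba"]] - sm[["qaly_tau"]]
  structure(list(
    iterations = it,
    summary = c(sm, inc_cost = inc_cost, inc_qaly = inc_qaly),
    icer_of_means = icer(inc_cost, inc_qaly),
    n_redraws = n_redraws, seed = seed, n = n,
    perspective = perspective, durability = durability, scenario = scenario
  ), class = "cea_psa")
}

#' @export
print.cea_psa <- function(x, ...) {
  cat(sprintf("Probabilistic analysis: %d iterations (%s, %s, seed %d, %d redraws)\n",
              x$n, x$perspective, x$durability, x$seed, x$n_redraws))
  s <- x$summary
  cat(sprintf("  mean ABA cost %s, QALYs %.2f; mean TAU cost %s, QALYs %.2f\n",
              .fmt_gbp(s[["cost_aba"]]), s[["qaly_aba"]],
              .fmt_gbp(s[["cost_tau"]]), s[["qaly_tau"]]))
  cat(sprintf("  mean incrementals: cost %s, QALYs %.4f\n",
              .fmt_gbp(s[["inc_cost"]]), s[["inc_qaly"]]))
  if (x$icer_of_means$status == "icer")
    cat(sprintf("  ICER of mean incrementals: %s per QALY\n", .fmt_gbp(x$icer_of_means$value)))
  else cat(sprintf("  ICER of mean incrementals: %s\n", x$icer_of_means$status))
  invisible(x)
}

#' Cost-effectiveness plane
#'
#' Scatter of incremental cost against incremental QALYs over the PSA
#' iterations, with the willingness-to-pay line(s).
#'
#' @param x a `cea_psa` object.
#' @param wtp threshold line(s) to draw (GBP/QALY).
#' @param ... passed to [graphics::plot()].
#' @export
plot.cea_psa <- function(x, wtp = c(20000, 30000), ...) {
  dq <- x$iterations$qaly_aba - x$iterations$qaly_tau
  dc <- x$iterations$cost_aba - x$iterations$cost_tau
  graphics::plot(dq, dc, pch = 16, cex = 0.3, col = grDevices::adjustcolor("steelblue", 0.4),
                 xlab = "Incremental QALYs", ylab = "Incremental cost (GBP)",
                 main = "Cost-effectiveness plane", ...)
  graphics::abline(h = 0, v = 0, col = "grey60")
  for (w in wtp) graphics::abline(0, w, lty = 2)
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability that the intervention
#' is cost-effective across PSA iterations.  The default criterion is
#' positive incremental net monetary benefit
#' (`wtp * inc_qaly - inc_cost > 0`), which handles dominance coherently;
#' `rule = "icer"` applies the literal ratio comparison
#' `inc_cost/inc_qaly < wtp` (as a spreadsheet implementation would),
#' which misclassifies dominated iterations.
#'
#' @param psa a `cea_psa` object.
#' @param wtp_grid willingness-to-pay values (GBP/QALY).
#' @param rule `"nmb"` (default) or `"icer"`.
#' @return object of class `cea_ceac`: data frame with columns `wtp`,
#'   `p_cost_effective`.
#' @export
ceac <- function(psa, wtp_grid = NULL, rule = c("nmb", "icer")) {
  stopifnot(inherits(psa, "cea_psa"), nrow(psa$iterations) > 0)
  rule <- match.arg(rule)
  if (is.null(wtp_grid)) wtp_grid <- .default_settings()$wtp_grid
  dq <- psa$iterations$qaly_aba - psa$iterations$qaly_tau
  dc <- psa$iterations$cost_aba - psa$iterations$cost_tau
  p <- vapply(wtp_grid, function(w) {
    if (rule == "nmb") mean(w * dq - dc > 0) else mean(dc / dq < w)
  }, numeric(1))
  structure(data.frame(wtp = wtp_grid, p_cost_effective = p),
            rule = rule, class = c("cea_ceac", "data.frame"))
}

#' @export
plot.cea_ceac <- function(x, ...) {
  graphics::plot(x$wtp, x$p_cost_effective, type = "l", lwd = 2, ylim = c(0, 1),
                 xlab = "Willingness to pay (GBP/QALY)",
                 ylab = "P(cost-effective)", main = "Cost-effectiveness acceptability", ...)
  graphics::abline(h = c(0, 1), col = "grey80")
  invisible(x)
}
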