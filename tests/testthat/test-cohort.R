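test_that("TAU scores drift linearly from baseline", {
  expect_equal(tau_score(0, 59.43, -0.28), 59.43)
  expect_equal(tau_score(12, 59.43, -0.28), 59.15)
  expect_equal(tau_score(120, 63.19, -0.45), 58.69)
  expect_error(tau_score(-1, 50, 0))
})

test_that("treatment effect ramps, persists or washes out as configured", {
  # linear ramp to the year-1 effect
  expect_equal(treatment_effect(6, 9.16, 14.13, "optimistic"), 4.58)
  expect_equal(treatment_effect(6, 9.16, 14.13, "pessimistic"), 4.58)
  expect_equal(treatment_effect(12, 9.16, 14.13, "optimistic"), 9.16)
  expect_equal(treatment_effect(24, 9.16, 14.13, "pessimistic"), 14.13)
  # beyond treatment: persistence vs linear washout to zero at month 84
  expect_equal(treatment_effect(48, 9.16, 14.13, "optimistic"), 14.13)
  expect_equal(treatment_effect(48, 9.16, 14.13, "pessimistic", 84), 14.13 * (84 - 48) / 60)
  expect_equal(treatment_effect(84, 9.16, 14.13, "pessimistic", 84), 0)
  expect_equal(treatment_effect(150, 9.16, 14.13, "pessimistic", 84), 0)
  expect_error(treatment_effect(30, 1, 2, "pessimistic", washout_end = 20), "washout")
})

test_that("trajectories compose TAU drift and treatment effect", {
  p <- dp()
  aba <- build_trajectory(p, "ABA", "optimistic")
  expect_equal(aba$iq[25], (59.43 - 0.28 * 2) + 14.13)   # month 24
  tau1 <- build_trajectory(p, "TAU", "optimistic")
  tau2 <- build_trajectory(p, "TAU", "pessimistic")
  expect_equal(tau1$iq, tau2$iq)                          # TAU ignores durability
  expect_equal(aba$iq[1], tau1$iq[1])                     # identical starting cohorts
  expect_equal(aba$vabs[1], tau1$vabs[1])
  # null effect collapses ABA onto TAU
  p0 <- p
  for (nm in c("eff_y1_vabs", "eff_y1_iq", "eff_y2_vabs", "eff_y2_iq"))
    p0$tbl[nm, c("mean", "se", "dist")] <- list(0, 0, "fixed")
  p0$tbl[c("eff_y1_vabs", "eff_y1_iq", "eff_y2_vabs", "eff_y2_iq"), c("lower", "upper")] <- NA
  aba0 <- build_trajectory(validate_parameters(p0), "ABA", "optimistic")
  expect_equal(aba0$iq, tau1$iq)
  expect_equal(aba0$vabs, tau1$vabs)
})

test_that("score ordering holds across perturbed inputs: optimistic >= pessimistic >= TAU", {
  for (seed in 1:5) {
    p <- make_fixture(dp(), perturbation = 0.5, seed = seed)
    # keep effects positive as the ordering premise requires
    for (nm in c("eff_y1_vabs", "eff_y1_iq", "eff_y2_vabs", "eff_y2_iq"))
      p$tbl[nm, "mean"] <- abs(p$tbl[nm, "mean"])
    tau <- build_trajectory(p, "TAU", "pessimistic")
    pes <- build_trajectory(p, "ABA", "pessimistic")
    opt <- build_trajectory(p, "ABA", "optimistic")
    expect_true(all(opt$iq >= pes$iq - 1e-12))
    expect_true(all(pes$iq >= tau$iq - 1e-12))
    expect_true(all(opt$vabs >= pes$vabs - 1e-12))
    expect_true(all(pes$vabs >= tau$vabs - 1e-12))
    # identical up to the end of treatment
    expect_equal(opt$iq[1:25], pes$iq[1:25])
  }
})

test_that("discounting and half-cycle accumulation behave as closed forms", {
  expect_equal(discount_factor(0, 0.035), 1)
  expect_equal(discount_factor(12, 0.035), 1 / 1.035)
  expect_equal(discount_factor(7, 0), 1)
  # conservation at zero rate
  expect_equal(accumulate(rep(1 / 12, 12), 0), 1)
  # single-cycle closed form: v discounted at the cycle midpoint
  v <- numeric(24); v[18] <- 100  # cycle t = 17
  expect_equal(accumulate(v, 0.035), 100 * 1.035^(-17.5 / 12))
  # discounting strictly decreases a constant flow, continuously in the rate
  flows <- rep(1, 120)
  rates <- c(0, 0.01, 0.035, 0.07)
  tot <- vapply(rates, function(r) accumulate(flows, r), numeric(1))
  expect_true(all(diff(tot) < 0))
  # annual stepping agrees at rate 0 and differs little at 3.5%
  expect_equal(accumulate(flows, 0, "annual"), accumulate(flows, 0, "monthly"))
  expect_lt(abs(accumulate(flows, 0.035, "annual") / accumulate(flows, 0.035, "monthly") - 1), 0.01)
})
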