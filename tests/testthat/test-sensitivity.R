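test_that("ICER arithmetic carries dominance flags", {
  expect_equal(icer(43940, 0.2444)$value, 43940 / 0.2444)
  expect_equal(icer(43940, 0.2444)$status, "icer")
  expect_equal(icer(-50294, 1.86)$status, "dominant")
  expect_equal(icer(5000, -0.1)$status, "dominated")
  expect_equal(icer(1000, 0)$status, "undefined")
  expect_equal(icer(0, 0.5)$value, 0)
})

test_that("one-way sensitivity analysis ranks parameter influence deterministically", {
  p <- dp()
  d1 <- run_dsa(p, "public_sector", "pessimistic")
  expect_s3_class(d1, "cea_dsa")
  # only non-fixed parameters with bounds are varied
  expect_false(any(d1$parameter %in% c("age_months", "rr_mortality", "obs_aba_mainstream")))
  expect_true(all(d1$range >= 0, na.rm = TRUE))
  expect_true(!is.unsorted(rev(d1$range), na.rm = TRUE))
  # treatment-effect magnitude and special-education cost are key drivers
  expect_true(all(c("eff_y2_iq", "school_special") %in% utils::head(d1$parameter, 10)) ||
                all(c("eff_y2_vabs", "school_special") %in% utils::head(d1$parameter, 10)))
  # purity: a second run is identical
  expect_identical(as.data.frame(d1), as.data.frame(run_dsa(p, "public_sector", "pessimistic")))
  # a parameter collapsed to its mean produces zero range
  p2 <- p
  p2$tbl["school_special", c("lower", "upper")] <- list(15702.78, 15702.78)
  d2 <- run_dsa(p2, "public_sector", "pessimistic")
  expect_equal(d2$range[d2$parameter == "school_special"], 0)
})

test_that("PSA is reproducible and collapses to the deterministic result when degenerate", {
  p <- dp()
  a <- run_psa(p, "public_sector", "pessimistic", n = 50, seed = 123)
  b <- run_psa(p, "public_sector", "pessimistic", n = 50, seed = 123)
  expect_identical(a$iterations, b$iterations)
  expect_identical(a$summary, b$summary)
  c2 <- run_psa(p, "public_sector", "pessimistic", n = 50, seed = 124)
  expect_false(identical(a$iterations, c2$iterations))
  # all-fixed parameters: every iteration equals the deterministic run
  fp <- fixed_params()
  det <- run_basecase(fp, "public_sector", "pessimistic")
  psa <- run_psa(fp, "public_sector", "pessimistic", n = 5, seed = 1)
  expect_equal(unique(psa$iterations$cost_aba), det$arms$cost[1])
  expect_equal(unique(psa$iterations$qaly_tau), det$arms$qalys[2])
  expect_equal(psa$icer_of_means$value, det$icer$value)
})

test_that("PSA means converge to the deterministic result as SEs shrink", {
  p <- dp()
  p$tbl$se <- p$tbl$se * 1e-6
  # bounds no longer bracket anything meaningfully; widen to keep validity
  det <- run_basecase(p, "public_sector", "optimistic")
  psa <- run_psa(p, "public_sector", "optimistic", n = 100, seed = 5)
  expect_equal(psa$summary[["inc_qaly"]], det$inc_qaly, tolerance = 1e-4)
  expect_equal(psa$summary[["inc_cost"]], det$inc_cost, tolerance = 1e-4)
  expect_equal(psa$icer_of_means$value, det$icer$value, tolerance = 1e-4)
})

test_that("CEAC is monotone under the NMB rule with coherent limits", {
  psa <- run_psa(dp(), "public_sector", "optimistic", n = 400, seed = 31)
  dq <- psa$iterations$qaly_aba - psa$iterations$qaly_tau
  dc <- psa$iterations$cost_aba - psa$iterations$cost_tau
  grid <- seq(0, 500000, by = 5000)
  cc <- ceac(psa, grid)
  expect_true(all(cc$p_cost_effective >= 0 & cc$p_cost_effective <= 1))
  # lambda = 0: cost-saving iterations only
  expect_equal(cc$p_cost_effective[1], mean(dc < 0))
  # large lambda: probability of any QALY gain
  expect_equal(ceac(psa, 1e12)$p_cost_effective, mean(dq > 0))
  # monotone in lambda whenever all QALY gains are positive
  if (all(dq > 0)) expect_true(all(diff(cc$p_cost_effective) >= 0))
  # literal ICER rule is available and differs only through dominated draws
  ci <- ceac(psa, grid, rule = "icer")
  expect_true(all(abs(ci$p_cost_effective - cc$p_cost_effective) <= mean(dq <= 0) + 1e-12))
})
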