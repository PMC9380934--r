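test_that("default parameter set carries the documented inputs and validates", {
  p <- dp()
  expect_s3_class(p, "aba_parameters")
  expect_equal(param_mean(p, "iq0"), 59.43)
  expect_equal(param_mean(p, "vabs0"), 63.19)
  expect_equal(param_mean(p, "ados0"), 6.98)
  expect_equal(param_mean(p, "cost_aba_annual"), 36682.78)
  expect_equal(param_mean(p, "school_special"), 15702.78)
  # completeness: every input block of the analysis is represented
  blocks <- unique(param_table(p)$block)
  expect_true(all(c("baseline", "natural_history", "effect_y1", "effect_y2",
                    "education_primary", "education_secondary",
                    "placement_observed", "utility", "costs", "adult_costs",
                    "mortality") %in% blocks))
  manifest <- c("prop_male", "prop_intellectual_disability", "age_months",
                "vabs0", "iq0", "ados0", "d_vabs_per_year", "d_iq_per_year",
                "eff_y1_vabs", "eff_y1_iq", "eff_y2_vabs", "eff_y2_iq",
                "edu_pri_vabs", "edu_pri_iq", "edu_pri_cut1", "edu_pri_cut2",
                "edu_sec_vabs", "edu_sec_iq", "edu_sec_cut1", "edu_sec_cut2",
                "obs_aba_mainstream", "obs_aba_supported", "obs_aba_special",
                "obs_tau_mainstream", "obs_tau_supported", "obs_tau_special",
                "u_const", "u_age", "u_age2", "u_ados", "u_logiq", "u_vabs",
                "cost_aba_annual", "cost_tau_annual", "socmed_intercept",
                "socmed_vabs", "socmed_iq", "school_mainstream",
                "school_supported", "school_special", "adult_own_home",
                "adult_sheltered_low", "adult_sheltered_high",
                "adult_residential", "adult_day_services", "adult_respite",
                "adult_employment", "adult_education", "adult_hospital",
                "adult_other", "rr_mortality")
  expect_setequal(param_table(p)$name, manifest)
  # bounds bracket means everywhere they exist
  tab <- param_table(p)
  has <- !is.na(tab$lower) & !is.na(tab$upper)
  expect_true(all(tab$lower[has] <= tab$mean[has] & tab$mean[has] <= tab$upper[has]))
})

test_that("validation rejects malformed parameter sets", {
  p <- dp()
  expect_error(set_parameter(p, "iq0", mean = 70), "outside")
  expect_error(set_parameter(p, "iq0", se = -1), "se must be")
  expect_error(set_parameter(p, "no_such_parameter", mean = 1), "unknown parameter")
  # se = 0 iff fixed
  expect_error(set_parameter(p, "eff_y2_iq", se = 0), "if and only if")
  bad <- p; bad$settings$primary_end_months <- 10
  expect_error(validate_parameters(bad), "preschool_end < primary_end")
  # degenerate distributions are legal
  expect_s3_class(validate_parameters(fixed_params()), "aba_parameters")
})

test_that("config files round-trip and merge onto packaged defaults", {
  p <- dp()
  for (ext in c(".yaml", ".json")) {
    tmp <- tempfile(fileext = ext)
    write_parameters(p, tmp)
    q <- load_parameters(tmp)
    expect_equal(q$tbl, p$tbl)
    expect_equal(q$settings[names(p$settings)], p$settings)
    unlink(tmp)
  }
  # shipped default config equals the in-code defaults
  shipped <- system.file("extdata", "default_parameters.yaml", package = "abacea")
  expect_equal(load_parameters(shipped)$tbl, p$tbl)
  # partial configs keep defaults for everything not mentioned
  tmp <- tempfile(fileext = ".yaml")
  writeLines(c("parameters:", "  iq0:", "    mean: 60.0",
               "settings:", "  discount_rate_annual: 0.015"), tmp)
  q <- load_parameters(tmp)
  expect_equal(param_mean(q, "iq0"), 60.0)
  expect_equal(q$settings$discount_rate_annual, 0.015)
  expect_equal(param_mean(q, "vabs0"), 63.19)
  unlink(tmp)
  # bound violations surface with the offending field named
  tmp2 <- tempfile(fileext = ".yaml")
  writeLines(c("parameters:", "  iq0:", "    mean: 10.0"), tmp2)
  expect_error(load_parameters(tmp2), "iq0")
  unlink(tmp2)
})

test_that("gamma moment matching reproduces the requested mean and SE", {
  g <- gamma_moments(36682.78, 7336)
  expect_equal(unname(g["shape"]), (36682.78 / 7336)^2, tolerance = 1e-12)
  expect_equal(unname(g["scale"]), 7336^2 / 36682.78, tolerance = 1e-12)
  expect_equal(unname(g["shape"] * g["scale"]), 36682.78)        # mean
  expect_equal(unname(sqrt(g["shape"]) * g["scale"]), 7336)      # sd
  # mean = se gives an exponential
  expect_equal(unname(gamma_moments(5, 5)["shape"]), 1)
  expect_error(gamma_moments(-1, 1), "mean > 0")
  expect_error(gamma_moments(1, 0), "se > 0")
  # Monte Carlo round trip: sampled mean within 3 SEs of the mean
  set.seed(99)
  x <- rgamma(1e6, shape = g["shape"], scale = g["scale"])
  expect_lt(abs(mean(x) - 36682.78), 3 * 7336 / sqrt(1e6))
})

test_that("beta moment matching reproduces the requested moments", {
  b <- beta_moments(0.8757, 0.0147)
  expect_equal(unname(b["shape1"] / sum(b)), 0.8757, tolerance = 1e-12)
  v <- prod(b) / (sum(b)^2 * (sum(b) + 1))
  expect_equal(sqrt(v), 0.0147, tolerance = 1e-9)
  expect_error(beta_moments(0.5, 0.6), "se too large")
})
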