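test_that("ordered logit recovers known generator structure from simulated records", {
  # generate from an exact cumulative-logit model, then check recovery
  beta_true <- 0.15
  cuts_true <- c(5.5, 7.5, 9.0, 11.0)
  set.seed(202)
  n <- 5000
  vabs <- runif(n, 25, 95)
  cum <- vapply(cuts_true, function(k) plogis(k - beta_true * vabs), numeric(n))
  u <- runif(n)
  lev_idx <- rowSums(u > cum) + 1L   # 1 = most dependent ... 5 = most independent
  levels_asc <- c("completely_dependent", "mostly_dependent", "some_independence",
                  "mostly_independent", "completely_independent")
  ipd <- data.frame(vabs = vabs, level = factor(levels_asc[lev_idx], levels = levels_asc))
  fit <- fit_independence_model(ipd)
  # polr orients latent index as beta * x with P(Y <= k) = plogis(zeta_k - eta)
  expect_lt(abs(fit$beta_vabs - beta_true) / beta_true, 0.10)
  expect_true(all(abs(fit$cuts - cuts_true) < 0.5))
  expect_true(all(diff(fit$cuts) > 0))
})

test_that("generator-driven recovery preserves level ordering and null effects", {
  ipd <- simulate_adult_ipd(n = 5000, seed = 11)
  fit <- fit_independence_model(ipd)
  expect_gt(fit$beta_vabs, 0)   # higher VABS -> more independent
  # monotone ordering: mean VABS rises with fitted independence level
  mv <- tapply(ipd$vabs, ipd$level, mean)
  expect_true(all(diff(mv) > 0))
  # flat generator (all level means equal): beta CI covers zero
  flat <- simulate_adult_ipd(n = 2000, level_means = rep(60, 5), level_sd = 10, seed = 12)
  f0 <- fit_independence_model(flat)
  expect_lt(abs(f0$beta_vabs), 1.96 * f0$se_beta)
})

test_that("degenerate records are rejected", {
  one_level <- data.frame(vabs = rnorm(100, 50, 5), level = "completely_dependent")
  expect_error(fit_independence_model(one_level), "at least 2 levels")
  few <- data.frame(vabs = rnorm(10), level = rep(c("completely_dependent", "mostly_dependent"), 5))
  expect_error(fit_independence_model(few), "at least 50")
})

test_that("independence mixes are simplex-valid and monotone in VABS", {
  model <- structure(list(beta_vabs = 0.15, cuts = c(5.5, 7.5, 9.0, 11.0),
                          se_beta = NA, levels = NULL, provenance = "supplied"),
                     class = "independence_model")
  vgrid <- seq(20, 130, by = 10)
  mixes <- t(vapply(vgrid, function(v) independence_mix(model, v), numeric(5)))
  expect_equal(rowSums(mixes), rep(1, nrow(mixes)))
  expect_true(all(mixes >= 0))
  # cumulative probability of dependence never rises with VABS
  for (k in 1:4) expect_true(all(diff(rowSums(mixes[, 1:k, drop = FALSE])) <= 1e-12))
  # logistic limit: extreme VABS concentrates on full independence
  expect_gt(independence_mix(model, 200)["completely_independent"], 0.999)
})

test_that("adult cost bundles decrease with independence", {
  b <- adult_bundle_costs(dp())
  expect_equal(unname(b["completely_independent"]), 0)
  expect_true(all(diff(b) <= 0))  # vector runs from most dependent to most independent
})

test_that("lifetime extension reduces to childhood at a zero adult horizon", {
  p <- dp()
  p$settings$max_age_years <- 18.5
  lt <- run_basecase(p, "public_sector", "pessimistic", "adult")
  ch <- run_basecase(p, "public_sector", "pessimistic", "base")
  expect_equal(lt$arms$cost, ch$arms$cost, tolerance = 1e-12)
  expect_equal(lt$arms$qalys, ch$arms$qalys, tolerance = 1e-12)
})

test_that("lifetime scenario: pessimistic ICER unchanged, optimistic dominant", {
  p <- dp()
  base_p <- run_basecase(p, "public_sector", "pessimistic", "base")
  life_p <- run_basecase(p, "public_sector", "pessimistic", "adult")
  # effects have fully converged by 18.5, so adult flows cancel exactly
  expect_equal(life_p$inc_cost, base_p$inc_cost, tolerance = 1e-9)
  expect_equal(life_p$inc_qaly, base_p$inc_qaly, tolerance = 1e-9)
  expect_equal(life_p$icer$value, base_p$icer$value, tolerance = 1e-9)
  life_o <- run_basecase(p, "public_sector", "optimistic", "adult")
  expect_equal(life_o$icer$status, "dominant")
  expect_lt(life_o$inc_cost, 0)
  expect_gt(life_o$inc_qaly, run_basecase(p, "public_sector", "optimistic")$inc_qaly)
})
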