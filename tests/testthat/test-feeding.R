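test_that("K1 follows the conversion allometry and its limits", {
  # direct evaluations of 1 - (W / 319)^0.0328
  expect_equal(k1_at_mass(0.046, gp0, cp0), 1 - (0.046 / 319)^0.0328,
               tolerance = 1e-12)
  expect_equal(k1_at_mass(0.046, gp0, cp0), 0.252, tolerance = 1e-3)
  expect_equal(k1_at_mass(1, gp0, cp0), 0.172, tolerance = 1e-2)
  expect_equal(k1_at_mass(319, gp0, cp0), 0)
  # decreasing in W, contained in [0, 1)
  k1 <- k1_at_mass(seq(0.05, 319, length.out = 200), gp0, cp0)
  expect_true(all(diff(k1) < 0))
  expect_true(all(k1 >= 0 & k1 < 1))
  expect_error(k1_at_mass(-1, gp0, cp0), "positive")
  expect_error(k1_at_mass(400, gp0, cp0), "asymptotic")
})

test_that("conversion_params checks the energy-density consistency", {
  expect_warning(conversion_params(jelly_factor = 12), "differs")
  expect_silent(conversion_params())
})

test_that("consumption_rate matches the chain evaluation and its limit", {
  # hatchling: dW/dt / K1, evaluated independently
  t <- 0
  x <- exp(-gp0$k * (t - gp0$t0))
  dwdt <- gp0$w_inf * gp0$b * gp0$k * (1 - x)^(gp0$b - 1) * x
  k1 <- 1 - (mass_at_age(t, gp0) / gp0$w_inf)^cp0$beta
  expect_equal(consumption_rate(t, gp0, cp0, "diet"), dwdt / k1,
               tolerance = 1e-10)
  # ~9 g diet/day, ~0.09 kg jellyfish/day at hatch
  expect_equal(consumption_rate(0, gp0, cp0, "diet") / 365.25, 0.009,
               tolerance = 0.05)
  expect_equal(consumption_rate(0, gp0, cp0, "jellyfish") / 365.25, 0.09,
               tolerance = 0.05)
  # asymptotic limit k W_inf / beta, x10 for jellyfish
  lim <- 0.299 * 319 / 0.0328
  expect_equal(consumption_rate(1e6, gp0, cp0, "diet"), lim)
  expect_equal(consumption_rate(1e6, gp0, cp0, "jellyfish"), 10 * lim)
  # ~80 kg jellyfish/day for an asymptotic adult
  expect_equal(10 * lim / 1000 / 365.25 * 1000, 79.6, tolerance = 0.01)
  # continuity at the limit: general formula at W = 0.999 W_inf
  t999 <- gp0$t0 - log(1 - 0.999^(1 / gp0$b)) / gp0$k
  expect_equal(consumption_rate(t999, gp0, cp0, "diet"), lim,
               tolerance = 2e-3)
  expect_true(all(is.finite(consumption_rate(seq(0, 500, 5), gp0, cp0))))
})

test_that("an adult of 250 kg eats about 65 kg of jellyfish per day", {
  t250 <- uniroot(function(t) mass_at_age(t, gp0) - 250, c(1, 60))$root
  ration <- consumption_rate(t250, gp0, cp0, "jellyfish") / 365.25
  expect_equal(ration, 65, tolerance = 0.05)
})

test_that("cumulative consumption is additive and zero on empty intervals", {
  expect_equal(cumulative_consumption(5, 5, gp0, cp0), 0)
  expect_error(cumulative_consumption(10, 5, gp0, cp0), "reversed")
  a <- cumulative_consumption(0, 7, gp0, cp0)
  b <- cumulative_consumption(7, 40, gp0, cp0)
  expect_equal(a + b, cumulative_consumption(0, 40, gp0, cp0),
               tolerance = 1e-6)
})

test_that("growth over an interval equals the integral of F * K1 (conservation)", {
  f_k1 <- function(t) {
    consumption_rate(t, gp0, cp0, "diet") *
      k1_at_mass(mass_at_age(t, gp0), gp0, cp0)
  }
  for (iv in list(c(0, 1), c(2, 7), c(10, 30))) {
    gain <- mass_at_age(iv[2], gp0) - mass_at_age(iv[1], gp0)
    expect_equal(integrate(f_k1, iv[1], iv[2], rel.tol = 1e-10)$value, gain,
                 tolerance = 1e-6)
  }
})

test_that("fit_beta recovers the conversion constant", {
  # noiseless records: exact recovery
  spec <- cohort_sim_spec(n_animals = 5, duration_yr = 4, sd_k = 0,
                          sd_mass = 0, sd_food = 0, seed = 3)
  cohort <- simulate_cohort(spec)
  # summary() warns about the (intentionally) perfect noiseless fit
  fit <- suppressWarnings(fit_beta(cohort$feeding, gp0))
  expect_equal(fit$beta, 0.0328, tolerance = 1e-6)
  # noisy records: within 2 SE in nearly all replicates (a single
  # replicate's 2-SE check is itself only a ~95% event)
  hits <- vapply(1:5, function(r) {
    specn <- cohort_sim_spec(n_animals = 20, duration_yr = 100 / 52,
                             sd_k = 0, sd_mass = 0, sd_food = 0.05,
                             seed = 200 + r)
    fitn <- fit_beta(simulate_cohort(specn)$feeding, gp0)
    abs(fitn$beta - 0.0328) < 2 * fitn$se
  }, logical(1))
  expect_gte(sum(hits), 4)
})

test_that("fit_beta excludes impossible records with a warning", {
  spec <- cohort_sim_spec(n_animals = 3, duration_yr = 2, sd_k = 0,
                          sd_mass = 0, sd_food = 0, seed = 9)
  rec <- simulate_cohort(spec)$feeding
  rec$food_wet_kg[3] <- 0                                  # zero food
  rec$mass_end_kg[10] <- rec$mass_start_kg[10] + 2 * rec$food_wet_kg[10]
  w <- capture_warnings(fit <- fit_beta(rec, gp0))
  expect_match(w, "excluded", all = FALSE)
  expect_equal(fit$n_excluded, 2)
  expect_equal(fit$beta, 0.0328, tolerance = 1e-4)
})

test_that("metabolic rate declines from hatchling to adult", {
  expect_equal(metabolic_rate(0, gp0, cp0, mp0), 2.15, tolerance = 0.02)
  # closed-form adult limit: k W_inf / beta * E_diet * avail / W_inf, in W/kg
  lim <- (0.299 * 319 / 0.0328) * 2.016 * 1000 * 0.63 /
    31557600 * 1000 / 319
  expect_equal(metabolic_rate(1e6, gp0, cp0, mp0), lim, tolerance = 1e-10)
  expect_equal(lim, 0.37, tolerance = 0.01)
  # scaling: zero available energy means zero MR
  mp_zero <- metabolic_params(total_available = 0)
  expect_equal(metabolic_rate(c(0, 5, 30), gp0, cp0, mp_zero), rep(0, 3))
  # monotone decrease past age 0.5 yr
  mr <- metabolic_rate(seq(0.5, 40, by = 0.5), gp0, cp0, mp0)
  expect_true(all(diff(mr) < 0))
})

test_that("whole-body energy and the budget cross-check reproduce print values", {
  expect_equal(body_energy(319, 0.712, 21.1), 319 * 0.288 * 21.1,
               tolerance = 1e-12)
  expect_equal(body_energy(319, 0.712, 21.1), 1938, tolerance = 0.001)
  expect_equal(body_energy(100, 1 - 1e-12, 21.1), 0, tolerance = 1e-6)
  expect_equal(body_energy(638, 0.712, 21.1),
               2 * body_energy(319, 0.712, 21.1))
  cons <- consumption_from_energy_budget(1938, 0.0328, 0.2)
  expect_equal(cons, 295, tolerance = 0.01)
  expect_gt(cons, 291); expect_lt(cons, 332)
  expect_equal(consumption_from_energy_budget(1938, 2 * 0.0328, 0.2),
               cons / 2)
  expect_error(consumption_from_energy_budget(1938, 0), "positive")
})

test_that("assay summaries converge on the generating values", {
  assays <- simulate_energy_assays(1000, seed = 21)
  s <- assay_summary(assays)
  expect_lt(abs(s$mean_energy - 20.16), 2 * 0.58 / sqrt(1000))
  expect_lt(abs(s$mean_dry_fraction - 0.10), 3 * 0.01 / sqrt(1000))
  expect_equal(s$sd_energy, 0.58, tolerance = 0.1)
  expect_warning(s1 <- assay_summary(assays[1, ]), "single")
  expect_true(is.na(s1$sd_energy))
})
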