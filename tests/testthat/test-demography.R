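np <- nesting_table_pacific()

test_that("hatchling production reproduces the nesting-table products", {
  by_pop <- hatchling_production(np, "mean", by_population = TRUE)
  expect_equal(unname(by_pop["EP"]), 19837, tolerance = 1e-4)
  expect_equal(unname(by_pop["WP"]), 108193, tolerance = 1e-4)
  expect_equal(hatchling_production(np, "mean"), 128031, tolerance = 1e-4)
  expect_equal(hatchling_production(np, "low"), 41275, tolerance = 1e-4)
  expect_equal(hatchling_production(np, "high"), 303578, tolerance = 1e-4)
  # zero nesters produce zero hatchlings
  np0 <- np
  np0$nesters <- 0
  expect_equal(hatchling_production(np0, "mean"), 0)
})

test_that("adult recruitment follows the first-timer arithmetic", {
  expect_equal(recruits_to_adults(np), 248 * 0.5 * 1.25 + 1113 * 0.5 * 2)
  expect_equal(recruits_to_adults(np), 1268, tolerance = 1e-3)
  expect_equal(recruits_to_adults(np, first_timer_fraction = 1),
               2 * recruits_to_adults(np))
})

test_that("mortality coefficients match their defining expression", {
  expect_equal(mortality_coefficient(32338, 1268, 15), -log(1268 / 32338) / 15)
  expect_equal(mortality_coefficient(32338, 1268, 15), 0.216,
               tolerance = 0.002)
  expect_equal(mortality_coefficient(10425, 1217, 15), 0.143,
               tolerance = 0.002)
  expect_equal(mortality_coefficient(100, 100, 7), 0)
  expect_error(mortality_coefficient(100, 150, 5), "negative")
  expect_equal(mortality_coefficient(100, 150, 5, allow_negative = TRUE),
               -log(1.5) / 5)
})

test_that("abundance at age follows the stage-wise exponentials", {
  s <- leatherback_schedule("mean")
  expect_equal(abundance_at_age(16, s), 1268, tolerance = 1e-3)
  # end of the hatchling stage (a stage owns [t_R, next t_R))
  expect_equal(abundance_at_age(1 - 1e-9, s),
               s$r[1] * exp(-1.38 * (1 - 0.0027)), tolerance = 1e-6)
  # ~25% first-year survival, and the printed yearling census
  expect_equal(abundance_at_age(1 - 1e-9, s) / 128031, 0.25,
               tolerance = 0.05)
  expect_equal(abundance_at_age(1, s), 32338)
  # boundary: N(t_R) = R on each stage
  expect_equal(abundance_at_age(s$t_r, s), s$r, tolerance = 1e-12)
  expect_error(abundance_at_age(0.001, s), "recruitment")
})

test_that("stage continuity holds exactly for derived (unrounded) Z values", {
  s <- leatherback_schedule("mean", rounded = FALSE)
  expect_equal(abundance_at_age(1 - 1e-12, s), s$r[2], tolerance = 1e-6)
  expect_equal(abundance_at_age(16 - 1e-12, s), s$r[3], tolerance = 1e-6)
})

test_that("stage summary gives S, A and half-lives consistent with Z", {
  s <- leatherback_schedule("mean")
  ss <- stage_summary(s)
  expect_equal(ss$annual_survival + ss$annual_mortality, rep(1, 3))
  expect_equal(ss$half_life_yr, c(0.5, 3.2, 3.0), tolerance = 0.01)
  expect_equal(ss$annual_mortality[1], 0.75, tolerance = 0.01)
  expect_equal(ss$annual_mortality[2], 0.19, tolerance = 0.03)
  expect_equal(ss$annual_mortality[3], 0.20, tolerance = 0.03)
  expect_equal(ss$annual_survival[2], 0.81, tolerance = 0.01)
  s0 <- stage_schedule("x", 0, 10, 0, 10)
  ss0 <- stage_summary(s0)
  expect_equal(ss0$annual_survival, 1)
  expect_equal(ss0$annual_mortality, 0)
  expect_true(is.infinite(ss0$half_life_yr))
})

test_that("discrete population totals match a brute-force cohort loop", {
  s <- leatherback_schedule("mean")
  pop <- total_population(s)
  # brute force: one pulse of hatchlings, then every integer-age cohort
  brute <- s$annual_production
  for (a in 1:15) brute <- brute + 32338 * exp(-0.216 * (a - 1))
  for (a in 16:46) brute <- brute + 1268 * exp(-0.229 * (a - 16))
  expect_equal(pop$total, brute, tolerance = 1e-12)
  # published census family
  expect_equal(pop$total, 294088, tolerance = 0.005)
  expect_equal(pop$adults, 6199, tolerance = 0.01)
  expect_equal(pop$nesting_fraction, 0.0046, tolerance = 0.02)
  expect_equal(pop$one_in, 217, tolerance = 0.01)
})

test_that("population outputs are monotone in the demographic level", {
  pops <- lapply(c("low", "mean", "high"), function(lv) {
    total_population(leatherback_schedule(lv))
  })
  totals <- sapply(pops, `[[`, "total")
  adults <- sapply(pops, `[[`, "adults")
  expect_true(all(diff(totals) > 0))
  expect_true(all(diff(adults) > 0))
  expect_equal(totals[1], 114663, tolerance = 0.01)
  expect_equal(totals[3], 628875, tolerance = 0.01)
  expect_equal(adults[1], 4292, tolerance = 0.01)
  expect_equal(adults[3], 8103, tolerance = 0.01)
})

test_that("first-year survival of 25% is encoded by Z = 1.38 over ~1 yr", {
  expect_equal(exp(-1.38 * (1 - 0.0027)), 0.25, tolerance = 0.04)
})

test_that("nesting table validation catches bad input", {
  bad <- as.data.frame(np)
  bad$hatching_success[1] <- 1.4
  expect_error(as_nesting_params(bad), "fractions")
  swapped <- as.data.frame(np)
  swapped$eggs_per_nest[swapped$population == "EP" &
                          swapped$level == "low"] <- 1000
  expect_error(as_nesting_params(swapped), "ordered")
})
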