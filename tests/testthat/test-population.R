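sched <- leatherback_schedule("mean")
grid <- build_grid(sched, gp0, cp0)

test_that("the population grid is built from pointwise defining products", {
  expect_equal(grid$Q_t_per_yr, grid$N * grid$F_t_per_yr, tolerance = 1e-12)
  expect_equal(grid$B_t, grid$N * grid$mass_kg / 1000, tolerance = 1e-12)
  expect_true(all(grid$N >= 0 & grid$Q_t_per_yr >= 0 & grid$B_t >= 0))
  # biomass at maturity ~ recruits x entry mass
  i16 <- which.min(abs(grid$age_yr - 16))
  expect_equal(grid$B_t[i16], 1268 * mass_at_age(16, gp0) / 1000,
               tolerance = 1e-6)
})

test_that("integrated totals reproduce the published population numbers", {
  tot <- integrate_totals(grid)
  expect_equal(tot$consumption_t_per_yr, 2.1e6, tolerance = 0.15)
  expect_equal(tot$biomass_t, 21510, tolerance = 0.15)
  expect_equal(tot$energy_mj_per_yr, 4.2e8, tolerance = 0.15)
  # energy is exactly consumption x 200 MJ/t
  expect_equal(tot$energy_mj_per_yr, tot$consumption_t_per_yr * 200)
})

test_that("annual and continuous integration agree within 5%", {
  cont <- integrate_totals(grid)
  ann <- integrate_totals(grid, mode = "annual")
  expect_lt(abs(ann$consumption_t_per_yr / cont$consumption_t_per_yr - 1),
            0.05)
  expect_lt(abs(ann$biomass_t / cont$biomass_t - 1), 0.05)
})

test_that("age bands partition the totals additively", {
  bands <- list(c(0, 2), c(2, 7), c(7, 16), c(16, 40))
  shares <- lapply(bands, function(b) age_band_share(grid, b))
  q_sum <- sum(sapply(shares, `[[`, "consumption_t_per_yr"))
  b_sum <- sum(sapply(shares, `[[`, "biomass_t"))
  tot <- integrate_totals(grid)
  expect_equal(q_sum, tot$consumption_t_per_yr, tolerance = 1e-9)
  expect_equal(b_sum, tot$biomass_t, tolerance = 1e-9)
  whole <- age_band_share(grid, c(0, 40))
  expect_equal(whole$consumption_fraction, 1, tolerance = 1e-12)
  expect_equal(whole$biomass_fraction, 1, tolerance = 1e-12)
})

test_that("2-7-year-olds dominate consumption; adults contribute little", {
  juv <- age_band_share(grid, c(2, 8))     # integer ages 2..7
  expect_gt(juv$consumption_fraction, 0.5)
  expect_equal(juv$consumption_t_per_yr, 1.1e6, tolerance = 0.15)
  expect_equal(juv$biomass_t, 10936, tolerance = 0.15)
  adult <- age_band_share(grid, c(16, 40))
  expect_lt(adult$consumption_fraction, 0.09)
  expect_equal(adult$consumption_t_per_yr, 1.8e5, tolerance = 0.15)
  expect_equal(adult$biomass_t, 1951, tolerance = 0.15)
})

test_that("Q/B sits in the published range and implies ~26% body mass/day", {
  qb <- q_over_b(grid)
  expect_gt(qb$q_over_b, 87)
  expect_lt(qb$q_over_b, 113)
  expect_equal(qb$body_mass_fraction_per_day, 0.26, tolerance = 0.15)
  # closed-form oracle: a stationary adult-only population has
  # Q/B = 10 k / beta per unit biomass-year
  adults_only <- stage_schedule("adult", 0, 1000, 0, 40)
  g_ad <- build_grid(adults_only, gp0, cp0, max_age = 40)
  # force every animal to asymptotic mass so growth dilution vanishes
  g_ad$mass_kg <- gp0$w_inf
  g_ad$F_t_per_yr <- consumption_rate(1e9, gp0, cp0, "jellyfish") / 1000
  g_ad$Q_t_per_yr <- g_ad$N * g_ad$F_t_per_yr
  g_ad$B_t <- g_ad$N * g_ad$mass_kg / 1000
  expect_equal(q_over_b(g_ad)$q_over_b, 10 * gp0$k / cp0$beta / 1,
               tolerance = 1e-9)
})

test_that("totals scale linearly with hatchling production at fixed Z", {
  s2 <- sched
  s2$r <- sched$r * 2
  s2$annual_production <- sched$annual_production * 2
  g2 <- build_grid(s2, gp0, cp0)
  t1 <- integrate_totals(grid)
  t2 <- integrate_totals(g2)
  expect_equal(t2$consumption_t_per_yr, 2 * t1$consumption_t_per_yr,
               tolerance = 1e-12)
  expect_equal(t2$biomass_t, 2 * t1$biomass_t, tolerance = 1e-12)
})

test_that("restoration scenario scales consumption to ~61 Mt per year", {
  sc <- scenario_scale(grid, 180000, sched)
  expect_equal(sc$factor, 180000 / total_population(sched)$adults)
  expect_equal(sc$factor, 29.0, tolerance = 0.02)
  expect_equal(sc$consumption_t_per_yr, 61e6, tolerance = 0.15)
  # identity at the current adult count
  id <- scenario_scale(grid, total_population(sched)$adults, sched)
  expect_equal(id$factor, 1)
  expect_equal(id$consumption_t_per_yr,
               integrate_totals(grid)$consumption_t_per_yr)
})

test_that("foraging footprints follow the density arithmetic", {
  ff <- foraging_footprint(2.1167e6, areal_density_t_km2 = 105)
  expect_equal(ff$area_km2, 20159, tolerance = 0.001)
  big <- foraging_footprint(61e6, areal_density_t_km2 = 105)
  expect_gt(big$area_km2, 580000)
  vol <- foraging_footprint(2.1e6, volumetric_density_g_m3 = c(100, 1),
                            depth_m = 200)
  expect_equal(vol$volume_m3, c(2.1e10, 2.1e12))
  expect_equal(vol$area_km2, c(105, 10500))
  expect_error(foraging_footprint(1e6, areal_density_t_km2 = 0), "positive")
})

test_that("an empty population gives zero consumption and biomass", {
  g0 <- grid
  g0$N <- 0
  g0$Q_t_per_yr <- 0
  g0$B_t <- 0
  tot <- integrate_totals(g0)
  expect_equal(tot$consumption_t_per_yr, 0)
  expect_error(q_over_b(g0), "zero")
})
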