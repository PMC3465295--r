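#!/usr/bin/env Rscript
# Population-level consumption and biomass: the Q(t) and B(t) curves,
# integrated totals, age-band shares, Q/B, and the restoration and
# foraging-footprint scenarios.
#
# Writes results/population_grid.csv and results/population_summary.json.

suppressPackageStartupMessages({
  library(leatherback)
  library(jsonlite)
})
dir.create("results", showWarnings = FALSE)

gp <- growth_params()
cp <- conversion_params()
sched <- leatherback_schedule("mean")
grid <- build_grid(sched, gp, cp, step = 1 / 52, max_age = 40)
write_population_grid(grid, "results/population_grid.csv")

tot <- integrate_totals(grid)
qb <- q_over_b(grid)
bands <- list(`0-1` = c(0, 2), `2-7` = c(2, 8), `8-15` = c(8, 16),
              adults = c(16, 40))
shares <- lapply(bands, function(b) age_band_share(grid, b))
restore <- scenario_scale(grid, 180000, sched)
fp_area <- foraging_footprint(tot$consumption_t_per_yr,
                              areal_density_t_km2 = 105)
fp_restore <- foraging_footprint(restore$consumption_t_per_yr,
                                 areal_density_t_km2 = 105)
fp_vol <- foraging_footprint(tot$consumption_t_per_yr,
                             volumetric_density_g_m3 = c(100, 1),
                             depth_m = 200)

cat("Pacific population, mean schedule, central growth/conversion:\n")
cat(sprintf("  annual consumption: %.3g t jellyfish (%.3g MJ)\n",
            tot$consumption_t_per_yr, tot$energy_mj_per_yr))
cat(sprintf("  standing biomass:   %.0f t\n", tot$biomass_t))
cat(sprintf("  Q/B: %.0f per yr  (%.0f%% of body mass per day)\n",
            qb$q_over_b, 100 * qb$body_mass_fraction_per_day))
for (nm in names(shares)) {
  s <- shares[[nm]]
  cat(sprintf("  ages %-6s %5.1f%% of consumption (%.3g t/yr), biomass %6.0f t\n",
              nm, 100 * s$consumption_fraction, s$consumption_t_per_yr,
              s$biomass_t))
}
cat(sprintf("  restored to 180,000 adults: %.3g t jellyfish/yr (x%.1f)\n",
            restore$consumption_t_per_yr, restore$factor))
cat(sprintf("  footprint at 105 t/km2: %.0f km2 now, %.0f km2 restored\n",
            fp_area$area_km2, fp_restore$area_km2))
cat(sprintf("  footprint at 100-1 g/m3, 200 m: %.3g-%.3g m3 (%.0f-%.0f km2)\n",
            fp_vol$volume_m3[1], fp_vol$volume_m3[2], fp_vol$area_km2[1],
            fp_vol$area_km2[2]))

write_json(list(
  totals = tot, q_over_b = qb,
  band_shares = lapply(shares, function(s) s[c("consumption_t_per_yr",
                                               "consumption_fraction",
                                               "biomass_t",
                                               "biomass_fraction")]),
  restoration = restore[c("factor", "adults", "consumption_t_per_yr",
                          "biomass_t")],
  footprint = list(areal_km2 = fp_area$area_km2,
                   restored_km2 = fp_restore$area_km2,
                   volumetric_m3 = fp_vol$volume_m3,
                   volumetric_km2 = fp_vol$area_km2)
), "results/population_summary.json", auto_unbox = TRUE, digits = 6)
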