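#' Build an age grid of abundance, mass, consumption and biomass
#'
#' Evaluates the coupled individual and population models on a regular age
#' grid: abundance N(t) from the stage schedule, body mass W(t) from the
#' VBGF, individual jellyfish intake F(t), the population consumption curve
#' Q(t) = N(t) F(t) (t jellyfish per yr of age class) and the cohort
#' biomass curve B(t) = N(t) W(t) / 1000 (t).
#'
#' @param sched a [stage_schedule()].
#' @param gp a [growth_params()] object.
#' @param cp a [conversion_params()] object.
#' @param step grid step, yr; default weekly (1/52).
#' @param max_age top of the grid, yr; default 40 (model longevity).
#' @return data frame of class `population_grid` with columns `age_yr`,
#'   `N`, `mass_kg`, `F_t_per_yr`, `Q_t_per_yr`, `B_t`.
#' @export
build_grid <- function(sched, gp, cp, step = 1 / 52, max_age = 40) {
  stopifnot(inherits(sched, "stage_schedule"),
            inherits(gp, "growth_params"),
            inherits(cp, "conversion_params"), step > 0)
  if (max_age > sched$end_age) {
    stop("grid extends past the schedule's end age (", sched$end_age, ")")
  }
  if (gp$t0 > 0) stop("growth model starts after age 0")
  age <- seq(0, max_age, by = step)
  # the abundance model is undefined before the first recruitment (~1 day);
  # the grid holds N at the initial pulse there
  N <- abundance_at_age(pmax(age, sched$t_r[1]), sched)
  W <- mass_at_age(age, gp)
  f <- consumption_rate(age, gp, cp, units = "jellyfish") / 1000  # t/yr
  g <- data.frame(age_yr = age, N = N, mass_kg = W, F_t_per_yr = f,
                  Q_t_per_yr = N * f, B_t = N * W / 1000)
  class(g) <- c("population_grid", class(g))
  g
}

#' Integrated population totals
#'
#' Trapezoidal quadrature of the population consumption and biomass curves
#' over the full age grid: annual population consumption (t jellyfish/yr),
#' standing biomass (t), and the energy equivalent of consumption
#' (MJ/yr, at `jelly_energy_mj_per_t`, default 200 MJ/t = 0.2 kJ/g wet
#' mass).
#'
#' @param grid a [build_grid()] result covering ages 0 to the model
#'   longevity.
#' @param jelly_energy_mj_per_t energy per tonne of jellyfish, MJ.
#' @param mode `"continuous"` (trapezoid over the grid, default) or
#'   `"annual"` (midpoint sum over 1-yr age classes), provided because
#'   census-style published totals mix both conventions.
#' @return list with `consumption_t_per_yr`, `biomass_t`,
#'   `energy_mj_per_yr`.
#' @export
integrate_totals <- function(grid, jelly_energy_mj_per_t = 200,
                             mode = c("continuous", "annual")) {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "population_grid"))
  if (min(grid$age_yr) > 0 || max(grid$age_yr) < 40) {
    stop("grid must cover ages 0-40")
  }
  if (mode == "continuous") {
    q <- pracma::trapz(grid$age_yr, grid$Q_t_per_yr)
    b <- pracma::trapz(grid$age_yr, grid$B_t)
  } else {
    mids <- seq(0.5, max(grid$age_yr) - 0.5, by = 1)
    qf <- stats::approx(grid$age_yr, grid$Q_t_per_yr, mids)$y
    bf <- stats::approx(grid$age_yr, grid$B_t, mids)$y
    q <- sum(qf)
    b <- sum(bf)
  }
  list(consumption_t_per_yr = q, biomass_t = b,
       energy_mj_per_yr = q * jelly_energy_mj_per_t)
}

#' Consumption and biomass share of an age band
#'
#' Integrates the population consumption and biomass curves over an age
#' band `[a, b]` and reports the band totals and their fractions of the
#' full-grid totals. Note the age-class convention: "2-7-year-olds" are
#' every animal whose age has integer part 2..7, i.e. the band `c(2, 8)`.
#'
#' @param grid a [build_grid()] result.
#' @param band numeric length-2, `c(a, b)` with `a < b`, inside the grid.
#' @param jelly_energy_mj_per_t energy per tonne of jellyfish, MJ.
#' @return list with `consumption_t_per_yr`, `biomass_t`,
#'   `energy_mj_per_yr`, `consumption_fraction`, `biomass_fraction`.
#' @export
age_band_share <- function(grid, band, jelly_energy_mj_per_t = 200) {
  stopifnot(inherits(grid, "population_grid"), length(band) == 2L,
            band[1] < band[2])
  if (band[1] < min(grid$age_yr) || band[2] > max(grid$age_yr)) {
    stop("band outside the grid")
  }
  tot <- integrate_totals(grid, jelly_energy_mj_per_t)
  keep <- grid$age_yr >= band[1] & grid$age_yr <= band[2]
  age <- grid$age_yr[keep]
  # close the band exactly at its ends by linear interpolation
  if (age[1] > band[1] || age[length(age)] < band[2]) {
    age <- unique(sort(c(band[1], age, band[2])))
  }
  qf <- stats::approx(grid$age_yr, grid$Q_t_per_yr, age)$y
  bf <- stats::approx(grid$age_yr, grid$B_t, age)$y
  q <- pracma::trapz(age, qf)
  b <- pracma::trapz(age, bf)
  list(consumption_t_per_yr = q, biomass_t = b,
       energy_mj_per_yr = q * jelly_energy_mj_per_t,
       consumption_fraction = q / tot$consumption_t_per_yr,
       biomass_fraction = b / tot$biomass_t)
}

#' Consumption-to-biomass ratio Q/B
#'
#' Annual population consumption divided by standing biomass: how many
#' times per year the population consumes its own mass in jellyfish. The
#' daily fraction (body mass eaten per day) is Q/B divided by 365.
#'
#' @param grid a [build_grid()] result.
#' @return list with `q_over_b` (yr^-1) and `body_mass_fraction_per_day`.
#' @export
q_over_b <- function(grid) {
  tot <- integrate_totals(grid)
  if (tot$biomass_t <= 0) stop("zero standing biomass")
  qb <- tot$consumption_t_per_yr / tot$biomass_t
  list(q_over_b = qb, body_mass_fraction_per_day = qb / 365)
}

#' Scale the population to a target adult abundance
#'
#' Uniformly rescales abundance (preserving age structure) so that the
#' discrete-annual adult count equals `target_adults`, and returns the
#' scaled totals. Used for restoration scenarios (e.g. adults back to the
#' ~180,000 of two decades ago).
#'
#' @param grid a [build_grid()] result.
#' @param target_adults desired number of adults.
#' @param sched the [stage_schedule()] the grid was built from (supplies
#'   the current discrete adult count).
#' @return list with `factor`, `adults`, `consumption_t_per_yr`,
#'   `biomass_t`, `energy_mj_per_yr`, and `grid` (the rescaled grid).
#' @export
scenario_scale <- function(grid, target_adults, sched) {
  stopifnot(target_adults > 0, inherits(sched, "stage_schedule"))
  adults_now <- total_population(sched)$adults
  f <- target_adults / adults_now
  g2 <- grid
  g2$N <- g2$N * f
  g2$Q_t_per_yr <- g2$Q_t_per_yr * f
  g2$B_t <- g2$B_t * f
  tot <- integrate_totals(g2)
  c(list(factor = f, adults = target_adults), tot, list(grid = g2))
}

#' Foraging footprint of a consumption demand
#'
#' Area (or volume) of ocean whose jellyfish standing stock matches an
#' annual consumption: consumption divided by an areal prey density
#' (t km^-2), or by a volumetric density (g m^-3) giving a water volume
#' that an epipelagic foraging depth converts to an area.
#'
#' @param consumption_t_per_yr annual consumption, t jellyfish.
#' @param areal_density_t_km2 jellyfish density, t km^-2 (coastal-survey
#'   style); give either this or `volumetric_density_g_m3`.
#' @param volumetric_density_g_m3 jellyfish density, g m^-3
#'   (tow-survey style); vectorised over densities.
#' @param depth_m foraging depth used with the volumetric density, m.
#' @return for areal input, `list(area_km2 = ...)`; for volumetric input,
#'   `list(volume_m3 = ..., area_km2 = ...)`.
#' @export
foraging_footprint <- function(consumption_t_per_yr,
                               areal_density_t_km2 = NULL,
                               volumetric_density_g_m3 = NULL,
                               depth_m = 200) {
  stopifnot(consumption_t_per_yr > 0)
  if (!is.null(areal_density_t_km2)) {
    if (any(areal_density_t_km2 <= 0)) stop("density must be positive")
    return(list(area_km2 = consumption_t_per_yr / areal_density_t_km2))
  }
  if (is.null(volumetric_density_g_m3)) {
    stop("give an areal or a volumetric density")
  }
  if (any(volumetric_density_g_m3 <= 0) || depth_m <= 0) {
    stop("density and depth must be positive")
  }
  vol_m3 <- consumption_t_per_yr * 1e6 / volumetric_density_g_m3  # t -> g
  list(volume_m3 = vol_m3, area_km2 = vol_m3 / depth_m / 1e6)
}
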