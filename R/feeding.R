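# seconds in a Julian year; fixes the kJ/yr -> W conversion
SECONDS_PER_YEAR <- 31557600

#' Food-conversion and diet-energetics parameters
#'
#' Parameters of the gross food-conversion allometry
#' \eqn{K_1 = 1 - (W / W_\infty)^\beta} (the Pauly method) together with the
#' energetics of the captive gelatin diet and of wild gelatinous prey.
#' The gelatin diet holds about 2.016 kJ per g wet mass (20.16 kJ/g dry mass
#' at 90% water); typical jellyfish hold about 0.2 kJ/g wet mass, so one
#' unit of gelatin diet is energetically equivalent to `jelly_factor = 10`
#' units of jellyfish wet mass. The factor is a fixed model constant, not
#' recomputed from the energy densities (they must agree within ~1%).
#'
#' @param beta conversion-allometry constant (dimensionless, in (0, 1)).
#' @param diet_energy_wm energy density of the experimental diet,
#'   kJ per g wet mass.
#' @param jelly_energy_wm energy density of jellyfish, kJ per g wet mass.
#' @param jelly_factor gelatin-to-jellyfish wet-mass multiplier.
#' @return An object of class `conversion_params`.
#' @export
conversion_params <- function(beta = 0.0328, diet_energy_wm = 2.016,
                              jelly_energy_wm = 0.2, jelly_factor = 10) {
  stopifnot(beta > 0, beta < 1, diet_energy_wm > 0, jelly_energy_wm > 0,
            jelly_factor > 0)
  implied <- diet_energy_wm / jelly_energy_wm
  if (abs(implied - jelly_factor) / jelly_factor > 0.01) {
    warning(sprintf(
      "jelly_factor (%.3g) differs from diet/jelly energy ratio (%.3g) by >1%%",
      jelly_factor, implied))
  }
  structure(list(beta = beta, diet_energy_wm = diet_energy_wm,
                 jelly_energy_wm = jelly_energy_wm,
                 jelly_factor = jelly_factor),
            class = "conversion_params")
}

#' Digestive and assimilation efficiencies
#'
#' Fraction of ingested food energy available to metabolism. Digestive
#' efficiency (~0.8 for gelatinous prey) times assimilation efficiency
#' (~0.8, accounting for nitrogenous loss) gives the usable-energy fraction;
#' the conventional reported value 0.63 is kept as the default for
#' `total_available` rather than the product 0.64.
#'
#' @param digestive_efficiency fraction in (0, 1].
#' @param assimilation_efficiency fraction in (0, 1].
#' @param total_available usable-energy fraction applied in
#'   [metabolic_rate()]; defaults to 0.63.
#' @return An object of class `metabolic_params`.
#' @export
metabolic_params <- function(digestive_efficiency = 0.8,
                             assimilation_efficiency = 0.8,
                             total_available = 0.63) {
  stopifnot(digestive_efficiency > 0, digestive_efficiency <= 1,
            assimilation_efficiency > 0, assimilation_efficiency <= 1,
            total_available >= 0, total_available <= 1)
  structure(list(digestive_efficiency = digestive_efficiency,
                 assimilation_efficiency = assimilation_efficiency,
                 total_available = total_available),
            class = "metabolic_params")
}

#' Gross food-conversion efficiency at a given mass
#'
#' \eqn{K_1 = 1 - (W / W_\infty)^\beta}: the fraction of ingested wet food
#' mass converted into body mass. Decreasing in W, and approaches 0 as W
#' approaches \eqn{W_\infty}.
#'
#' @param W body mass, kg; in `(0, w_inf]`; vectorised.
#' @param gp a [growth_params()] object (supplies `w_inf`).
#' @param cp a [conversion_params()] object (supplies `beta`).
#' @return K1, dimensionless fraction in `[0, 1)`.
#' @export
k1_at_mass <- function(W, gp, cp) {
  stopifnot(inherits(gp, "growth_params"), inherits(cp, "conversion_params"))
  if (any(W <= 0)) stop("mass must be positive")
  if (any(W > gp$w_inf * (1 + 1e-12))) {
    stop("mass exceeds the asymptotic mass w_inf")
  }
  -expm1(cp$beta * log(pmin(W / gp$w_inf, 1)))
}

#' Fit the conversion-allometry constant beta from feeding records
#'
#' Each record gives mass at the start and end of an interval and the wet
#' food mass consumed over it. The observed conversion efficiency is
#' \eqn{K_1 = (W_j - W_i) / F} and is assigned to the interval's mean mass
#' \eqn{(W_i + W_j)/2}. beta is the slope of the through-the-origin linear
#' regression of \eqn{\log(1 - K_1)} on \eqn{\log(W / W_\infty)}.
#'
#' Records with zero food or with \eqn{K_1 \ge 1} (more mass gained than
#' food eaten, impossible except by observation error) are excluded with a
#' warning.
#'
#' @param records data frame with columns `animal_id`, `age_start_yr`,
#'   `age_end_yr`, `mass_start_kg`, `mass_end_kg`, `food_wet_kg`.
#' @param gp a [growth_params()] object (supplies `w_inf`).
#' @return list with `beta`, `se`, `n_used`, `n_excluded`, `fit` (the `lm`
#'   object) and `data` (the regression frame with `k1`, `mean_mass`).
#' @export
fit_beta <- function(records, gp) {
  stopifnot(is.data.frame(records),
            all(c("mass_start_kg", "mass_end_kg", "food_wet_kg")
                %in% names(records)),
            inherits(gp, "growth_params"))
  if (nrow(records) < 10L) {
    stop("need at least 10 feeding records to fit beta")
  }
  k1 <- (records$mass_end_kg - records$mass_start_kg) / records$food_wet_kg
  mean_mass <- (records$mass_start_kg + records$mass_end_kg) / 2
  bad <- !is.finite(k1) | k1 >= 1 | records$food_wet_kg <= 0 |
    mean_mass <= 0 | mean_mass > gp$w_inf
  if (any(bad)) {
    warning(sum(bad), " feeding record(s) excluded (K1 >= 1, zero food,",
            " or mass out of range)")
  }
  d <- data.frame(k1 = k1[!bad], mean_mass = mean_mass[!bad])
  if (diff(range(log10(d$mean_mass))) < 1) {
    warning("feeding records span less than one decade of mass;",
            " beta is weakly identified")
  }
  d$y <- log1p(-d$k1)
  d$x <- log(d$mean_mass / gp$w_inf)
  fit <- stats::lm(y ~ x + 0, data = d)
  co <- summary(fit)$coefficients
  list(beta = unname(co["x", "Estimate"]), se = unname(co["x", "Std. Error"]),
       n_used = nrow(d), n_excluded = sum(bad), fit = fit, data = d)
}

#' Individual food-intake rate as a function of age
#'
#' The rate of food consumption is growth divided by conversion efficiency:
#' \eqn{F(t) = (dW/dt) / K_1(W_t)}. In diet units this approaches the finite
#' limit \eqn{k W_\infty / \beta} as \eqn{W \to W_\infty} (the 0/0 is
#' resolved analytically); in jellyfish units it is multiplied by the
#' wet-mass equivalence factor (10 by default).
#'
#' @param t age, yr; `>= 0` (ages back to `t0` are accepted); vectorised.
#' @param gp a [growth_params()] object.
#' @param cp a [conversion_params()] object.
#' @param units `"diet"` (gelatin-diet wet mass) or `"jellyfish"`
#'   (jellyfish wet-mass equivalent).
#' @return intake rate, kg wet mass per yr.
#' @export
consumption_rate <- function(t, gp, cp, units = c("diet", "jellyfish")) {
  units <- match.arg(units)
  stopifnot(inherits(gp, "growth_params"), inherits(cp, "conversion_params"))
  if (any(t < gp$t0)) stop("age below t0")
  x <- exp(-gp$k * (t - gp$t0))          # -> 0 as t -> infinity
  # numerator dW/dt = w_inf b k (1-x)^(b-1) x; denominator K1 = 1-(1-x)^(b*beta)
  # both -> 0 as x -> 0; -expm1(b*beta*log1p(-x)) ~ b*beta*x keeps the ratio
  # stable, with the exact limit k*w_inf/beta patched in at x == 0.
  denom <- -expm1(gp$b * cp$beta * log1p(-x))
  f <- gp$w_inf * gp$b * gp$k * (1 - x)^(gp$b - 1) * x / denom
  f[x == 0 | denom == 0] <- gp$k * gp$w_inf / cp$beta
  if (units == "jellyfish") f <- f * cp$jelly_factor
  f
}

#' Cumulative jellyfish consumption over an age interval
#'
#' Adaptive quadrature of [consumption_rate()] in jellyfish units between
#' two ages, returned in metric tonnes.
#'
#' @param t1,t2 interval bounds, yr, with `0 <= t1 <= t2`.
#' @param gp,cp growth and conversion parameter objects.
#' @param rel_tol relative quadrature tolerance.
#' @return total intake, t jellyfish wet mass.
#' @export
cumulative_consumption <- function(t1, t2, gp, cp, rel_tol = 1e-8) {
  stopifnot(length(t1) == 1L, length(t2) == 1L, t1 >= 0)
  if (t2 < t1) stop("reversed age interval")
  if (t2 == t1) return(0)
  q <- stats::integrate(function(u) consumption_rate(u, gp, cp, "jellyfish"),
                        t1, t2, rel.tol = rel_tol, subdivisions = 400L)
  q$value / 1000
}

#' Mass-specific metabolic rate derived from food intake
#'
#' Of the energy ingested at age t, a fraction \eqn{K_1} is banked as new
#' tissue and a fraction `total_available` of the remainder is usable;
#' the balance fuels metabolism:
#' \deqn{MR(t) = F(t) \, E_{diet} \, A \, (1 - K_1(W_t)) / W_t}
#' with F in diet units. The kJ/yr to W conversion uses a Julian year
#' (31,557,600 s).
#'
#' @inheritParams consumption_rate
#' @param mp a [metabolic_params()] object.
#' @return mass-specific metabolic rate, W kg^-1.
#' @export
metabolic_rate <- function(t, gp, cp, mp) {
  stopifnot(inherits(mp, "metabolic_params"))
  f_diet <- consumption_rate(t, gp, cp, "diet")          # kg/yr
  W <- mass_at_age(t, gp)
  k1 <- k1_at_mass(pmin(W, gp$w_inf), gp, cp)
  energy_kj_yr <- f_diet * cp$diet_energy_wm * 1000 *    # kJ/kg wet
    mp$total_available * (1 - k1)
  energy_kj_yr * (1000 / SECONDS_PER_YEAR) / W           # W per kg
}

#' Whole-body energy content
#'
#' Body mass times dry fraction times tissue energy density:
#' `mass * (1 - water_fraction) * tissue_energy_dm`, in MJ
#' (kg wet x kJ/g dry = MJ).
#'
#' @param mass body mass, kg.
#' @param water_fraction total body water fraction, in (0, 1).
#' @param tissue_energy_dm energy density of homogenised tissue,
#'   kJ per g dry mass.
#' @return whole-body energy, MJ.
#' @export
body_energy <- function(mass, water_fraction, tissue_energy_dm) {
  stopifnot(all(mass > 0), all(tissue_energy_dm > 0))
  if (any(water_fraction < 0 | water_fraction >= 1)) {
    stop("water_fraction must lie in [0, 1)")
  }
  mass * (1 - water_fraction) * tissue_energy_dm
}

#' Energy-budget cross-check of cumulative consumption
#'
#' Independent route to the jellyfish tonnage needed to build a body of a
#' given energy content: body energy divided by the mean gross conversion
#' constant and the jellyfish energy per tonne. With 0.2 kJ/g wet mass
#' (200 MJ/t) and beta = 0.0328 this cross-validates the quadrature of
#' [cumulative_consumption()] from hatch to maturity.
#'
#' @param body_energy_mj whole-body energy, MJ (see [body_energy()]).
#' @param mean_beta mean gross conversion constant over development.
#' @param jelly_energy_wm jellyfish energy density, kJ per g wet mass.
#' @return consumption, t jellyfish wet mass.
#' @export
consumption_from_energy_budget <- function(body_energy_mj, mean_beta,
                                           jelly_energy_wm = 0.2) {
  stopifnot(all(body_energy_mj > 0), jelly_energy_wm > 0)
  if (any(mean_beta <= 0)) stop("mean_beta must be positive")
  mj_per_tonne <- jelly_energy_wm * 1000   # kJ/g == MJ/kg; x1000 -> MJ/t
  body_energy_mj / (mean_beta * mj_per_tonne)
}

#' Summarise bomb-calorimetry assays
#'
#' Arithmetic mean and SD of dry fraction and dry-mass energy density over
#' a set of food-sample assays.
#'
#' @param assays data frame with columns `sample_id`, `dry_fraction`,
#'   `energy_kj_per_g_dm`.
#' @return list with `n`, `mean_dry_fraction`, `sd_dry_fraction`,
#'   `mean_energy`, `sd_energy`. With a single assay the SDs are `NA` (a
#'   warning is raised).
#' @export
assay_summary <- function(assays) {
  stopifnot(is.data.frame(assays),
            all(c("dry_fraction", "energy_kj_per_g_dm") %in% names(assays)))
  if (nrow(assays) < 1L) stop("no assays")
  if (nrow(assays) == 1L) {
    warning("single assay: SD is undefined")
  }
  list(n = nrow(assays),
       mean_dry_fraction = mean(assays$dry_fraction),
       sd_dry_fraction = stats::sd(assays$dry_fraction),
       mean_energy = mean(assays$energy_kj_per_g_dm),
       sd_energy = stats::sd(assays$energy_kj_per_g_dm))
}
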