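#' Specification of a synthetic captive feeding trial
#'
#' Defines the simulated cohort: hatchlings raised for `duration_yr` years,
#' weighed on a fixed cadence (weekly by default), with every feeding
#' interval's wet food mass recorded. Individual variation enters through
#' the growth parameter k only (each animal draws
#' \eqn{k_i = k \, e^{\epsilon}}, \eqn{\epsilon \sim N(0, sd_k)}), keeping
#' b and W_inf shared across animals. Mass observations carry
#' multiplicative lognormal noise of relative SD `sd_mass`; food records
#' carry multiplicative lognormal noise of relative SD `sd_food` (food is
#' a positive measured residue difference).
#'
#' @param n_animals number of animals (default 20, a typical clutch-sized
#'   captive cohort).
#' @param duration_yr trial length, yr (default 2).
#' @param cadence_yr measurement interval, yr (default weekly, 1/52).
#' @param gp true [growth_params()].
#' @param cp true [conversion_params()].
#' @param sd_k lognormal SD of individual variation in k (default 0.05).
#' @param sd_mass relative observation SD on mass (default 0.02).
#' @param sd_food relative observation SD on food (default 0.05).
#' @param seed integer seed.
#' @return An object of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n_animals = 20, duration_yr = 2,
                            cadence_yr = 1 / 52,
                            gp = growth_params(), cp = conversion_params(),
                            sd_k = 0.05, sd_mass = 0.02, sd_food = 0.05,
                            seed = 1) {
  stopifnot(n_animals >= 1, duration_yr > 0, cadence_yr > 0,
            sd_k >= 0, sd_mass >= 0, sd_food >= 0,
            inherits(gp, "growth_params"), inherits(cp, "conversion_params"))
  structure(list(n_animals = as.integer(n_animals),
                 duration_yr = duration_yr, cadence_yr = cadence_yr,
                 gp = gp, cp = cp, sd_k = sd_k, sd_mass = sd_mass,
                 sd_food = sd_food, seed = as.integer(seed)),
            class = "cohort_sim_spec")
}

#' Simulate a captive cohort: weekly masses and feeding records
#'
#' Per animal: draw \eqn{k_i}, follow the VBGF trajectory, observe masses
#' with noise, and record for each interval the wet food mass implied by
#' the conversion model -- true mass gain divided by \eqn{K_1} at the
#' interval's true mean mass -- perturbed by food observation noise.
#' Observed masses are internally consistent: the mass ending one feeding
#' interval starts the next.
#'
#' @param spec a [cohort_sim_spec()].
#' @return list with `masses` (data frame `animal_id`, `age_yr`,
#'   `mass_kg`) and `feeding` (data frame `animal_id`, `age_start_yr`,
#'   `age_end_yr`, `mass_start_kg`, `mass_end_kg`, `food_wet_kg`), plus
#'   attribute `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  set.seed(spec$seed)
  gp <- spec$gp
  ages <- seq(0, spec$duration_yr, by = spec$cadence_yr)
  masses <- vector("list", spec$n_animals)
  feeding <- vector("list", spec$n_animals)
  for (i in seq_len(spec$n_animals)) {
    k_i <- gp$k * exp(stats::rnorm(1, 0, spec$sd_k))
    gp_i <- growth_params(w_inf = gp$w_inf, k = k_i, t0 = gp$t0,
                          b = gp$b, a = gp$a)
    true_w <- mass_at_age(ages, gp_i)
    obs_w <- true_w * exp(stats::rnorm(length(ages), 0, spec$sd_mass))
    if (any(obs_w <= 0)) stop("simulation produced non-positive masses")
    n_int <- length(ages) - 1L
    true_gain <- diff(true_w)
    mean_true_w <- (true_w[-1] + true_w[-length(true_w)]) / 2
    true_food <- true_gain / k1_at_mass(mean_true_w, gp, spec$cp)
    obs_food <- true_food * exp(stats::rnorm(n_int, 0, spec$sd_food))
    id <- sprintf("T%02d", i)
    masses[[i]] <- data.frame(animal_id = id, age_yr = ages,
                              mass_kg = obs_w)
    feeding[[i]] <- data.frame(animal_id = id,
                               age_start_yr = ages[-length(ages)],
                               age_end_yr = ages[-1],
                               mass_start_kg = obs_w[-length(obs_w)],
                               mass_end_kg = obs_w[-1],
                               food_wet_kg = obs_food)
  }
  out <- list(masses = do.call(rbind, masses),
              feeding = do.call(rbind, feeding))
  attr(out, "spec") <- spec
  out
}

#' Simulate bomb-calorimetry assays of the diet
#'
#' Draws dry fractions and dry-mass energy densities around their true
#' values (normal, truncated positive by redraw).
#'
#' @param n number of assays.
#' @param dry_fraction true dry fraction (default 0.10).
#' @param energy true energy density, kJ per g dry mass (default 20.16).
#' @param sd SD of the energy density (default 0.58).
#' @param sd_dry SD of the dry fraction (default 0.01).
#' @param seed integer seed (`NULL` leaves the RNG state alone).
#' @return data frame `sample_id`, `dry_fraction`, `energy_kj_per_g_dm`.
#' @export
simulate_energy_assays <- function(n, dry_fraction = 0.10, energy = 20.16,
                                   sd = 0.58, sd_dry = 0.01, seed = NULL) {
  stopifnot(n >= 1, dry_fraction > 0, dry_fraction < 1, energy > 0,
            sd >= 0, sd_dry >= 0)
  if (!is.null(seed)) set.seed(seed)
  draw_pos <- function(n, mean, sd, upper = Inf) {
    x <- stats::rnorm(n, mean, sd)
    while (any(bad <- (x <= 0 | x >= upper))) {
      x[bad] <- stats::rnorm(sum(bad), mean, sd)
    }
    x
  }
  data.frame(sample_id = sprintf("A%04d", seq_len(n)),
             dry_fraction = draw_pos(n, dry_fraction, sd_dry, upper = 1),
             energy_kj_per_g_dm = draw_pos(n, energy, sd))
}

#' Write the default fixture set to a directory
#'
#' Writes the Pacific nesting-ecology table, a simulated cohort (mass
#' series and feeding records) and a simulated assay set as CSV files,
#' all generated under one seed so two calls with the same seed produce
#' byte-identical files.
#'
#' @param out_dir writable directory (created if missing).
#' @param seed integer seed.
#' @param spec cohort specification; defaults to [cohort_sim_spec()] with
#'   the given seed.
#' @param n_assays number of simulated assays.
#' @return invisibly, the paths written.
#' @export
make_fixture_set <- function(out_dir, seed = 1,
                             spec = cohort_sim_spec(seed = seed),
                             n_assays = 50) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(spec)
  assays <- simulate_energy_assays(n_assays, seed = seed + 1L)
  paths <- c(
    nesting = file.path(out_dir, "nesting_pacific.csv"),
    masses = file.path(out_dir, "cohort_masses.csv"),
    feeding = file.path(out_dir, "cohort_feeding.csv"),
    assays = file.path(out_dir, "energy_assays.csv")
  )
  np <- nesting_table_pacific()
  utils::write.csv(as.data.frame(np), paths["nesting"], row.names = FALSE)
  write_mass_series(cohort$masses, paths["masses"])
  write_feeding_records(cohort$feeding, paths["feeding"])
  write_energy_assays(assays, paths["assays"])
  invisible(paths)
}
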