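#' Monte Carlo specification for parameter uncertainty
#'
#' Distributions for the fitted growth and conversion parameters used in
#' Monte Carlo propagation: normal draws for beta, b and k at their fitted
#' means and SEMs, and (optionally) uniform draws of the asymptotic mass
#' over its estimated range. W_inf is fixed at its central value by
#' default, matching a resampling scheme over (beta, b, k) only;
#' `sample_w_inf = TRUE` adds the range as a fourth source of spread.
#'
#' @param draws number of Monte Carlo runs (>= 100; default 10,000).
#' @param seed integer seed for reproducibility (`NULL` leaves the RNG
#'   state alone).
#' @param beta_mean,beta_se Normal distribution of the conversion constant.
#' @param b_mean,b_se Normal distribution of the length--mass exponent.
#' @param k_mean,k_se Normal distribution of the VBGF k.
#' @param w_inf central asymptotic mass, kg.
#' @param w_inf_range uniform range for W_inf when `sample_w_inf = TRUE`.
#' @param sample_w_inf draw W_inf from `w_inf_range` instead of fixing it.
#' @param hatchling_mass anchor for t0 in every run, kg.
#' @return An object of class `mc_spec`.
#' @export
mc_spec <- function(draws = 10000, seed = NULL,
                    beta_mean = 0.0328, beta_se = 0.001,
                    b_mean = 2.86, b_se = 0.014,
                    k_mean = 0.299, k_se = 0.001,
                    w_inf = 319, w_inf_range = c(267, 379),
                    sample_w_inf = FALSE, hatchling_mass = 0.046) {
  stopifnot(draws >= 100, beta_se > 0, b_se > 0, k_se > 0,
            length(w_inf_range) == 2L, w_inf_range[1] < w_inf_range[2])
  structure(list(draws = as.integer(draws), seed = seed,
                 beta_mean = beta_mean, beta_se = beta_se,
                 b_mean = b_mean, b_se = b_se,
                 k_mean = k_mean, k_se = k_se,
                 w_inf = w_inf, w_inf_range = w_inf_range,
                 sample_w_inf = sample_w_inf,
                 hatchling_mass = hatchling_mass),
            class = "mc_spec")
}

#' Draw parameter sets for the Monte Carlo runs
#'
#' Independent draws: beta, b, k ~ Normal(mean, SE); W_inf either fixed or
#' ~ Uniform over its range. Draws that land outside the model's domain
#' (non-positive beta or k, b outside (2, 4)) are rejected and redrawn,
#' with a message reporting how many.
#'
#' @param spec an [mc_spec()].
#' @return data frame with columns `beta`, `b`, `k`, `w_inf`
#'   (`spec$draws` rows).
#' @export
sample_parameters <- function(spec) {
  stopifnot(inherits(spec, "mc_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$draws
  draw <- function(n) {
    data.frame(
      beta = stats::rnorm(n, spec$beta_mean, spec$beta_se),
      b = stats::rnorm(n, spec$b_mean, spec$b_se),
      k = stats::rnorm(n, spec$k_mean, spec$k_se),
      w_inf = if (spec$sample_w_inf) {
        stats::runif(n, spec$w_inf_range[1], spec$w_inf_range[2])
      } else rep(spec$w_inf, n)
    )
  }
  d <- draw(n)
  bad <- d$beta <= 0 | d$k <= 0 | d$b <= 2 | d$b >= 4
  n_redrawn <- 0L
  while (any(bad)) {
    n_redrawn <- n_redrawn + sum(bad)
    d[bad, ] <- draw(sum(bad))
    bad <- d$beta <= 0 | d$k <= 0 | d$b <= 2 | d$b >= 4
  }
  if (n_redrawn > 0L) {
    message(n_redrawn, " out-of-domain draw(s) rejected and redrawn")
  }
  d
}

# evaluate one target curve for one parameter draw
mc_curve <- function(target, age, gp, cp, sched, mp) {
  switch(target,
    consumption = consumption_rate(age, gp, cp, "jellyfish") / 1000,
    population_consumption = {
      N <- abundance_at_age(pmax(age, sched$t_r[1]), sched)
      N * consumption_rate(age, gp, cp, "jellyfish") / 1000
    },
    biomass = {
      N <- abundance_at_age(pmax(age, sched$t_r[1]), sched)
      N * mass_at_age(age, gp) / 1000
    },
    metabolic_rate = metabolic_rate(age, gp, cp, mp)
  )
}

#' Monte Carlo envelope for a model curve
#'
#' Propagates the parameter distributions through the chosen model curve:
#' individual jellyfish consumption (t/yr), population consumption
#' Q(t) (t/yr), population biomass B(t) (t), or mass-specific metabolic
#' rate (W/kg). For every grid age, runs are ranked and the central 95%
#' kept (lowest and highest 2.5% excluded); the mean of runs and the
#' plug-in curve (central parameters) are reported alongside. Each run's
#' age-integral gives the distribution of the integrated total.
#'
#' @param spec an [mc_spec()].
#' @param target `"consumption"`, `"population_consumption"`, `"biomass"`
#'   or `"metabolic_rate"`.
#' @param sched [stage_schedule()] for the population targets.
#' @param mp [metabolic_params()] for the metabolic-rate target.
#' @param cp_template conversion parameters whose energy densities are
#'   reused in every run (beta is replaced by each draw).
#' @param step,max_age age grid, yr.
#' @return list with `age` grid; `envelope` data frame
#'   (`age_yr`, `mean`, `lo95`, `hi95`, `plug_in`); `total` list with the
#'   run-mean, 95% CI and plug-in value of the age-integral; `draws` (the
#'   parameter draws).
#' @export
monte_carlo_envelope <- function(spec,
                                 target = c("consumption",
                                            "population_consumption",
                                            "biomass", "metabolic_rate"),
                                 sched = NULL, mp = NULL,
                                 cp_template = conversion_params(),
                                 step = 1 / 52, max_age = 40) {
  target <- match.arg(target)
  stopifnot(inherits(spec, "mc_spec"))
  if (target %in% c("population_consumption", "biomass") &&
      !inherits(sched, "stage_schedule")) {
    stop("population targets need a stage schedule")
  }
  if (target == "metabolic_rate" && !inherits(mp, "metabolic_params")) {
    stop("the metabolic-rate target needs metabolic_params")
  }
  d <- sample_parameters(spec)
  age <- seq(0, max_age, by = step)
  runs <- matrix(NA_real_, nrow = spec$draws, ncol = length(age))
  integrals <- numeric(spec$draws)
  for (i in seq_len(spec$draws)) {
    gp_i <- growth_params(w_inf = d$w_inf[i], k = d$k[i], b = d$b[i],
                          hatchling_mass = spec$hatchling_mass)
    cp_i <- conversion_params(beta = d$beta[i],
                              diet_energy_wm = cp_template$diet_energy_wm,
                              jelly_energy_wm = cp_template$jelly_energy_wm,
                              jelly_factor = cp_template$jelly_factor)
    runs[i, ] <- mc_curve(target, age, gp_i, cp_i, sched, mp)
    integrals[i] <- pracma::trapz(age, runs[i, ])
  }
  gp0 <- growth_params(w_inf = spec$w_inf, k = spec$k_mean, b = spec$b_mean,
                       hatchling_mass = spec$hatchling_mass)
  cp0 <- conversion_params(beta = spec$beta_mean,
                           diet_energy_wm = cp_template$diet_energy_wm,
                           jelly_energy_wm = cp_template$jelly_energy_wm,
                           jelly_factor = cp_template$jelly_factor)
  plug_in <- mc_curve(target, age, gp0, cp0, sched, mp)

  n <- spec$draws
  lo_i <- floor(0.025 * n) + 1L
  hi_i <- ceiling(0.975 * n)
  bounds <- apply(runs, 2, function(x) sort(x)[c(lo_i, hi_i)])
  env <- data.frame(age_yr = age,
                    mean = colMeans(runs),
                    lo95 = bounds[1, ],
                    hi95 = bounds[2, ],
                    plug_in = plug_in)
  ints <- sort(integrals)
  list(age = age, envelope = env,
       total = list(mean = mean(integrals),
                    lo95 = ints[lo_i], hi95 = ints[hi_i],
                    plug_in = pracma::trapz(age, plug_in)),
       draws = d)
}

#' Deterministic low/mean/high demographic scenarios
#'
#' Builds the three stage schedules from the low, mean and high
#' nesting-ecology rows (+/-2 SEM products) and propagates each through
#' the full pipeline: hatchling production, yearlings, recruits, mortality
#' coefficients, discrete population totals, and (given growth and
#' conversion parameters) integrated population consumption and biomass.
#'
#' @param np a nesting-parameters table ([nesting_table_pacific()]).
#' @param gp,cp growth and conversion parameters for the consumption and
#'   biomass totals.
#' @param rounded use conventional rounded Z values (see
#'   [leatherback_schedule()]).
#' @param step,max_age grid for the integrated totals.
#' @param ... further arguments passed to [leatherback_schedule()].
#' @return list with `schedules` (named list of [stage_schedule()]s) and
#'   `summary` (data frame, one row per level).
#' @export
demographic_bounds <- function(np = nesting_table_pacific(),
                               gp = growth_params(),
                               cp = conversion_params(),
                               rounded = TRUE, step = 1 / 52, max_age = 40,
                               ...) {
  levels <- c("low", "mean", "high")
  schedules <- lapply(levels, function(lv) {
    leatherback_schedule(level = lv, rounded = rounded, np = np, ...)
  })
  names(schedules) <- levels
  rows <- lapply(levels, function(lv) {
    s <- schedules[[lv]]
    pop <- total_population(s)
    grid <- build_grid(s, gp, cp, step = step, max_age = max_age)
    tot <- integrate_totals(grid)
    data.frame(level = lv,
               hatchlings = s$r[1], yearlings = s$r[2], recruits = s$r[3],
               z_hatchling = s$z[1], z_juvenile = s$z[2], z_adult = s$z[3],
               total_population = pop$total, adults = pop$adults,
               consumption_t_per_yr = tot$consumption_t_per_yr,
               biomass_t = tot$biomass_t)
  })
  list(schedules = schedules, summary = do.call(rbind, rows))
}
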