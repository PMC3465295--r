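#' Pacific leatherback nesting-ecology table
#'
#' The default nesting-ecology inputs for the eastern (EP) and western (WP)
#' Pacific populations, as compiled from the nesting-beach literature:
#' nesters per year, nests per female, eggs per nest, hatching success,
#' emergence rate, and first-day survival on the beach crawl and during the
#' frenzy swim. The `low`/`high` levels are +/-2 SEM (or the reported range
#' where no SEM exists) around the means.
#'
#' @param path optional path to a nesting-parameters CSV with columns
#'   `population,level,nesters,nests_per_female,eggs_per_nest,
#'   hatching_success,emergence,beach_survival,water_survival`; defaults to
#'   the table shipped with the package.
#' @return data frame of class `nesting_params`, one row per population x
#'   level.
#' @export
nesting_table_pacific <- function(path = system.file("extdata",
                                                     "nesting_pacific.csv",
                                                     package = "leatherback")) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_nesting_params(d)
}

#' Validate a nesting-parameters table
#'
#' @param d data frame with the nesting-parameter columns (see
#'   [nesting_table_pacific()]).
#' @return the validated data frame with class `nesting_params` prepended.
#' @export
as_nesting_params <- function(d) {
  needed <- c("population", "level", "nesters", "nests_per_female",
              "eggs_per_nest", "hatching_success", "emergence",
              "beach_survival", "water_survival")
  stopifnot(is.data.frame(d), all(needed %in% names(d)))
  fracs <- c("hatching_success", "emergence", "beach_survival",
             "water_survival")
  if (any(unlist(d[fracs]) < 0) || any(unlist(d[fracs]) > 1)) {
    stop("survival/success columns must be fractions in [0, 1]")
  }
  if (any(d$nesters < 0)) stop("nester counts must be non-negative")
  if (!all(d$level %in% c("low", "mean", "high"))) {
    stop("level must be one of low/mean/high")
  }
  # low <= mean <= high elementwise, per population
  num <- setdiff(needed, c("population", "level"))
  for (popn in unique(d$population)) {
    sub <- d[d$population == popn, ]
    lo <- sub[sub$level == "low", num]
    me <- sub[sub$level == "mean", num]
    hi <- sub[sub$level == "high", num]
    if (nrow(lo) == 1 && nrow(me) == 1 && nrow(hi) == 1 &&
        (any(lo > me) || any(me > hi))) {
      stop("levels must be ordered low <= mean <= high for population ", popn)
    }
  }
  class(d) <- c("nesting_params", class(d))
  d
}

#' Annual hatchling production
#'
#' Product of the seven nesting-ecology factors (nesters x nests/female x
#' eggs/nest x hatching success x emergence x beach survival x water
#' survival) per population, summed over populations. No intermediate
#' rounding.
#'
#' @param np a nesting-parameters table ([nesting_table_pacific()]).
#' @param level `"low"`, `"mean"` or `"high"`.
#' @param by_population return per-population numbers instead of the sum.
#' @return hatchlings entering the ocean per year.
#' @export
hatchling_production <- function(np, level = c("mean", "low", "high"),
                                 by_population = FALSE) {
  level <- match.arg(level)
  stopifnot(inherits(np, "nesting_params"))
  sub <- np[np$level == level, ]
  h <- sub$nesters * sub$nests_per_female * sub$eggs_per_nest *
    sub$hatching_success * sub$emergence * sub$beach_survival *
    sub$water_survival
  names(h) <- sub$population
  if (by_population) h else sum(h)
}

#' Annual recruitment to the adult population
#'
#' Number of turtles reaching maturity each year, back-calculated from the
#' nesting beaches: nesters per year times the fraction of first-time
#' nesters, times a population-specific sex multiplier (1.25 for a 4:1
#' female:male eastern Pacific, 2 for a 1:1 western Pacific).
#'
#' @param np a nesting-parameters table.
#' @param level nesting level used for the nester counts.
#' @param first_timer_fraction fraction of each year's nesters nesting for
#'   the first time (default 0.50).
#' @param sex_multiplier named vector of female-to-total multipliers keyed
#'   by population.
#' @return recruits (both sexes) per year.
#' @export
recruits_to_adults <- function(np, level = "mean", first_timer_fraction = 0.5,
                               sex_multiplier = c(EP = 1.25, WP = 2)) {
  stopifnot(inherits(np, "nesting_params"),
            first_timer_fraction > 0, first_timer_fraction <= 1,
            all(sex_multiplier >= 1))
  sub <- np[np$level == level, ]
  if (!all(sub$population %in% names(sex_multiplier))) {
    stop("sex_multiplier must name every population in the table")
  }
  sum(sub$nesters * first_timer_fraction *
        sex_multiplier[sub$population])
}

#' Instantaneous mortality coefficient from boundary abundances
#'
#' \eqn{Z = -\log(N_{end}/N_{start}) / \Delta t}, the exponential decay rate
#' that carries `n_start` individuals to `n_end` over `duration` years.
#'
#' @param n_start,n_end cohort sizes at the start and end of the stage
#'   (both positive).
#' @param duration stage duration, yr (> 0).
#' @param allow_negative permit `n_end > n_start` (a growing cohort gives
#'   negative Z); otherwise such input is an error.
#' @return Z, yr^-1.
#' @export
mortality_coefficient <- function(n_start, n_end, duration,
                                  allow_negative = FALSE) {
  stopifnot(all(n_start > 0), all(n_end > 0), all(duration > 0))
  if (!allow_negative && any(n_end > n_start)) {
    stop("n_end > n_start gives negative mortality;",
         " set allow_negative = TRUE if intended")
  }
  -log(n_end / n_start) / duration
}

#' Stage schedule for the exponential survivorship model
#'
#' Defines the piecewise abundance model
#' \eqn{N_t = R \, e^{-Z (t - t_R)}} over ordered life stages. Each stage
#' has a recruitment age `t_r`, a recruit count `r`, an instantaneous
#' mortality `z`, and an end age equal to the next stage's recruitment age
#' (the last stage's end age closes the model's longevity).
#'
#' @param stage character vector of stage names.
#' @param t_r recruitment ages, yr; strictly increasing.
#' @param r recruits entering each stage (> 0).
#' @param z instantaneous mortality per stage, yr^-1 (>= 0).
#' @param end_age end age of the final stage, yr.
#' @param annual_production annual hatchling production counted as the
#'   first (pulse) age class by [total_population()]; defaults to the
#'   first stage's `r`.
#' @return An object of class `stage_schedule`.
#' @seealso [leatherback_schedule()] for the default Pacific schedules.
#' @export
stage_schedule <- function(stage, t_r, r, z, end_age,
                           annual_production = r[1]) {
  stopifnot(length(stage) == length(t_r), length(t_r) == length(r),
            length(r) == length(z),
            all(diff(t_r) > 0), all(r > 0), all(z >= 0),
            length(end_age) == 1L, end_age > t_r[length(t_r)])
  structure(list(stage = as.character(stage), t_r = as.numeric(t_r),
                 r = as.numeric(r), z = as.numeric(z),
                 end_age = as.numeric(end_age),
                 annual_production = annual_production),
            class = "stage_schedule")
}

#' @export
print.stage_schedule <- function(x, ...) {
  cat("Stage schedule (N_t = R e^{-Z (t - t_R)}):\n")
  ends <- c(x$t_r[-1], x$end_age)
  for (i in seq_along(x$stage)) {
    cat(sprintf("  %-10s ages %6.4g-%-4.4g  R = %8.6g  Z = %.3f yr^-1\n",
                x$stage[i], x$t_r[i], ends[i], x$r[i], x$z[i]))
  }
  invisible(x)
}

#' Default Pacific leatherback stage schedules
#'
#' Builds the three-stage (hatchling / juvenile / adult) schedule for the
#' Pacific population at a given demographic level. Hatchlings recruit at
#' ~1 day (t_R = 0.0027 yr) with annual production from the nesting table;
#' 25% survive to age 1; juveniles decay to the adult recruit count at
#' maturity (16 yr); adults persist to the model longevity (16 + 31 yr).
#'
#' With `rounded = TRUE` (default) the conventional printed coefficients
#' are used (mean: Z = 1.38, 0.216, 0.229; low: 0.143, 0.333; high: 0.271,
#' 0.177), which reproduce the published population totals. With
#' `rounded = FALSE` every Z is derived from its boundary condition by
#' [mortality_coefficient()], making abundance exactly continuous across
#' stage boundaries.
#'
#' @param level `"mean"`, `"low"` or `"high"`.
#' @param rounded use the conventional rounded Z values (see Details).
#' @param np nesting-parameters table supplying hatchling production.
#' @param recruits named vector of annual adult recruits per level. The
#'   low/high values are literature-given bounds, not re-derived.
#' @param yearlings named vector of yearling census counts per level
#'   (the published census values, which differ by ~1% from
#'   `first_year_survival * hatchlings`), or `NULL` to derive them as
#'   `first_year_survival * hatchling production`.
#' @param adult_z named vector of adult mortality per level (the adult
#'   stage has no closing boundary condition; its Z is an input).
#' @param first_year_survival fraction of hatchlings alive at age 1; used
#'   only when `yearlings = NULL`.
#' @param maturity_age age at first reproduction, yr.
#' @param adult_years adult stage span, yr.
#' @return a [stage_schedule()].
#' @export
leatherback_schedule <- function(level = c("mean", "low", "high"),
                                 rounded = TRUE,
                                 np = nesting_table_pacific(),
                                 recruits = c(low = 1217, mean = 1268,
                                              high = 1318),
                                 yearlings = c(low = 10425, mean = 32338,
                                               high = 76679),
                                 adult_z = c(low = 0.333, mean = 0.229,
                                             high = 0.177),
                                 first_year_survival = 0.25,
                                 maturity_age = 16, adult_years = 31) {
  level <- match.arg(level)
  hatch <- hatchling_production(np, level)
  yearlings <- if (is.null(yearlings)) first_year_survival * hatch
               else unname(yearlings[level])
  rec <- unname(recruits[level])
  t_r0 <- 0.0027                      # ~1 day
  z_hatch <- mortality_coefficient(hatch, yearlings, 1 - t_r0)
  z_juv <- mortality_coefficient(yearlings, rec, maturity_age - 1)
  z_adu <- unname(adult_z[level])
  if (rounded) {
    z_hatch <- 1.38
    z_juv <- round(z_juv, 3)
  }
  stage_schedule(stage = c("hatchling", "juvenile", "adult"),
                 t_r = c(t_r0, 1, maturity_age),
                 r = c(hatch, yearlings, rec),
                 z = c(z_hatch, z_juv, z_adu),
                 end_age = maturity_age + adult_years,
                 annual_production = hatch)
}

#' Abundance at age under the stage-structured mortality model
#'
#' Evaluates \eqn{N_t = R \, e^{-Z (t - t_R)}} on the stage containing each
#' age. Ages before the first recruitment age are an error.
#'
#' @param t age, yr; vectorised.
#' @param sched a [stage_schedule()].
#' @return number of individuals alive at each age.
#' @export
abundance_at_age <- function(t, sched) {
  stopifnot(inherits(sched, "stage_schedule"), is.numeric(t))
  if (any(t < sched$t_r[1])) {
    stop("age before first recruitment (t_R = ", sched$t_r[1], ")")
  }
  idx <- findInterval(t, sched$t_r)
  sched$r[idx] * exp(-sched$z[idx] * (t - sched$t_r[idx]))
}

#' Per-stage survival, mortality and half-life
#'
#' From each stage's instantaneous mortality Z: annual survival
#' \eqn{S = e^{-Z}}, annual mortality \eqn{A = 1 - e^{-Z}}, and half-life
#' \eqn{\ln 2 / Z} (infinite when Z = 0).
#'
#' @param sched a [stage_schedule()].
#' @return data frame with columns `stage`, `z`, `annual_survival`,
#'   `annual_mortality`, `half_life_yr`.
#' @export
stage_summary <- function(sched) {
  stopifnot(inherits(sched, "stage_schedule"))
  data.frame(stage = sched$stage,
             z = sched$z,
             annual_survival = exp(-sched$z),
             annual_mortality = -expm1(-sched$z),
             half_life_yr = ifelse(sched$z > 0, log(2) / sched$z, Inf))
}

#' Total population size from discrete annual age classes
#'
#' Sums the stage-structured model over integer age classes: the annual
#' hatchling production (one pulse class), juvenile cohorts at each integer
#' age from 1 to maturity - 1, and adult cohorts at each integer age from
#' maturity to the end age - 1. This discrete-annual convention is the one
#' that reproduces published census-style totals; continuous integration of
#' the same curves gives slightly different numbers.
#'
#' @param sched a [stage_schedule()] (three stages:
#'   hatchling/juvenile/adult).
#' @param annual_nesters total nesting females per year, used for the
#'   nesting-fraction diagnostic (default: the Pacific total 248 + 1113).
#' @return list with `total`, `by_stage` (named vector), `adults`,
#'   `nesting_fraction` (annual nesters / total) and `one_in` (its
#'   reciprocal).
#' @export
total_population <- function(sched, annual_nesters = 1361) {
  stopifnot(inherits(sched, "stage_schedule"), length(sched$stage) == 3L)
  juv_ages <- seq(sched$t_r[2], sched$t_r[3] - 1)
  adult_ages <- seq(sched$t_r[3], sched$end_age - 1)
  counts <- c(sched$annual_production,
              sum(abundance_at_age(juv_ages, sched)),
              sum(abundance_at_age(adult_ages, sched)))
  names(counts) <- sched$stage
  total <- sum(counts)
  list(total = total, by_stage = counts, adults = counts[[3]],
       nesting_fraction = annual_nesters / total,
       one_in = total / annual_nesters)
}
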