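#' Von Bertalanffy growth parameters
#'
#' Bundles the parameters of the mass-based von Bertalanffy growth function
#' (VBGF), \eqn{W_t = W_\infty (1 - e^{-k (t - t_0)})^b}, together with the
#' length--mass relationship \eqn{W = a L^b} used to move between straight
#' carapace length (SCL, cm) and body mass (kg).
#'
#' Defaults are the central captive-stock estimates for Pacific leatherbacks:
#' \eqn{W_\infty} = 319 kg, k = 0.299 yr\eqn{^{-1}}, b = 2.86,
#' a = 2.14e-4 kg cm\eqn{^{-b}}. \eqn{t_0} is rarely reported for mass-based
#' VBGFs; when `t0 = NULL` it is anchored so that mass at age 0 equals
#' `hatchling_mass` (default 0.046 kg, a typical leatherback hatchling),
#' via [solve_t0()].
#'
#' @param w_inf asymptotic mass, kg.
#' @param k VBGF growth parameter, yr^-1 (not a growth rate).
#' @param t0 theoretical age at mass 0, yr, or `NULL` to anchor to
#'   `hatchling_mass` at age 0.
#' @param b length--mass exponent (dimensionless, close to 3).
#' @param a length--mass multiplier, kg cm^-b.
#' @param hatchling_mass mass at age 0 used to solve for `t0` when
#'   `t0 = NULL`, kg.
#'
#' @return An object of class `growth_params`: a list with elements
#'   `w_inf`, `k`, `t0`, `b`, `a`.
#' @examples
#' gp <- growth_params()
#' mass_at_age(c(0, 2, 16), gp)
#' @export
growth_params <- function(w_inf = 319, k = 0.299, t0 = NULL, b = 2.86,
                          a = 2.14e-4, hatchling_mass = 0.046) {
  stopifnot(is.numeric(w_inf), length(w_inf) == 1L, w_inf > 0,
            is.numeric(k), length(k) == 1L, k > 0,
            is.numeric(b), length(b) == 1L, b > 2, b < 4,
            is.numeric(a), length(a) == 1L, a > 0)
  p <- structure(list(w_inf = w_inf, k = k, t0 = NA_real_, b = b, a = a),
                 class = "growth_params")
  if (is.null(t0)) {
    p$t0 <- solve_t0(hatchling_mass, p)
  } else {
    stopifnot(is.numeric(t0), length(t0) == 1L, is.finite(t0))
    p$t0 <- t0
  }
  p
}

#' @export
print.growth_params <- function(x, ...) {
  cat("VBGF growth parameters:\n")
  cat(sprintf("  W_inf = %.4g kg, k = %.4g yr^-1, t0 = %.4g yr\n",
              x$w_inf, x$k, x$t0))
  cat(sprintf("  length-mass: W = %.3g * L^%.4g  (W kg, L cm SCL)\n",
              x$a, x$b))
  invisible(x)
}

#' Predicted body mass at age
#'
#' Evaluates the mass-based VBGF
#' \eqn{W_t = W_\infty (1 - e^{-k (t - t_0)})^b}. Strictly increasing in
#' age, approaching \eqn{W_\infty} asymptotically.
#'
#' @param t age, yr; vectorised. Must satisfy `t >= t0`.
#' @param p a [growth_params()] object.
#' @return mass, kg.
#' @export
mass_at_age <- function(t, p) {
  stopifnot(inherits(p, "growth_params"), is.numeric(t))
  if (any(t < p$t0)) {
    stop("age below t0 = ", format(p$t0),
         ": the VBGF base is negative there")
  }
  p$w_inf * (-expm1(-p$k * (t - p$t0)))^p$b
}

#' Growth rate (first derivative of the VBGF)
#'
#' \eqn{dW/dt = W_\infty b k (1 - e^{-k(t - t_0)})^{b-1} e^{-k(t - t_0)}}.
#' Non-negative, and declines to zero as mass approaches \eqn{W_\infty}.
#'
#' @inheritParams mass_at_age
#' @return growth rate, kg yr^-1.
#' @export
growth_rate <- function(t, p) {
  stopifnot(inherits(p, "growth_params"), is.numeric(t))
  if (any(t < p$t0)) {
    stop("age below t0 = ", format(p$t0))
  }
  x <- exp(-p$k * (t - p$t0))
  p$w_inf * p$b * p$k * (1 - x)^(p$b - 1) * x
}

#' Length--mass interconversion
#'
#' `mass_from_length()` evaluates \eqn{W = a L^b}; `length_from_mass()` its
#' inverse \eqn{L = (W/a)^{1/b}}. L is straight carapace length in cm,
#' W is mass in kg.
#'
#' @param L SCL, cm; positive, vectorised.
#' @param W mass, kg; positive, vectorised.
#' @param p a [growth_params()] object.
#' @return mass in kg, or length in cm.
#' @export
mass_from_length <- function(L, p) {
  stopifnot(inherits(p, "growth_params"), is.numeric(L))
  if (any(L <= 0)) stop("length must be positive")
  p$a * L^p$b
}

#' @rdname mass_from_length
#' @export
length_from_mass <- function(W, p) {
  stopifnot(inherits(p, "growth_params"), is.numeric(W))
  if (any(W <= 0)) stop("mass must be positive")
  (W / p$a)^(1 / p$b)
}

#' Anchor t0 to a hatchling mass
#'
#' Solves \eqn{W(0) = W_{hatch}} for \eqn{t_0} in closed form:
#' \eqn{t_0 = \log(1 - (W_{hatch}/W_\infty)^{1/b}) / k}. Negative whenever
#' the hatchling mass is positive.
#'
#' @param w_hatch hatchling mass at age 0, kg; must be in `(0, w_inf)`.
#' @param p a `growth_params` object (its `t0` is ignored).
#' @return t0, yr (<= 0).
#' @export
solve_t0 <- function(w_hatch, p) {
  stopifnot(is.numeric(w_hatch), length(w_hatch) == 1L)
  if (w_hatch < 0 || w_hatch >= p$w_inf) {
    stop("hatchling mass must lie in [0, w_inf)")
  }
  log1p(-(w_hatch / p$w_inf)^(1 / p$b)) / p$k
}

#' Fit the VBGF to mass-at-age data
#'
#' Nonlinear least squares fit of
#' \eqn{W_t = W_\infty (1 - e^{-k (t - t_0)})^b} to a mass-at-age series,
#' optionally on the log-mass scale (multiplicative error). Any of
#' `b`, `w_inf`, `t0` may be fixed; free parameters get standard errors from
#' the local curvature of the least-squares surface.
#'
#' @param data data frame with columns `animal_id`, `age_yr`, `mass_kg`
#'   (a mass-at-age series, e.g. from [simulate_cohort()] or
#'   [read_mass_series()]).
#' @param fixed named list of parameters to hold fixed; any of
#'   `b`, `w_inf`, `t0`. Defaults fix `b = 2.86` and `w_inf = 319`
#'   (the length--mass exponent and asymptote are estimated externally from
#'   the length--mass relationship), leaving `k` and `t0` free.
#' @param log_mass fit on log(mass) instead of mass (multiplicative
#'   residuals). Default `FALSE`.
#' @param a length--mass multiplier carried into the returned params.
#' @return list with elements `params` (a [growth_params()] object at the
#'   fitted values), `estimates` (data frame of estimate/SE per free
#'   parameter), `fit` (the underlying `nls` object), and `residuals`.
#' @export
fit_growth <- function(data, fixed = list(b = 2.86, w_inf = 319),
                       log_mass = FALSE, a = 2.14e-4) {
  stopifnot(is.data.frame(data),
            all(c("age_yr", "mass_kg") %in% names(data)))
  if (length(unique(data$age_yr)) < 6L) {
    stop("need at least 6 distinct ages to fit the VBGF")
  }
  if (any(data$mass_kg <= 0)) stop("masses must be positive")

  free <- setdiff(c("w_inf", "k", "t0", "b"), names(fixed))
  if (!("k" %in% free)) stop("k must be free")
  start <- list(w_inf = max(data$mass_kg) * 1.2, k = 0.3, t0 = -0.1,
                b = 3)[free]
  lower <- c(w_inf = max(data$mass_kg), k = 1e-4, t0 = -5, b = 2.01)[free]
  upper <- c(w_inf = 1e4, k = 5, t0 = 0, b = 3.99)[free]

  # fixed parameters travel in the data list alongside the observations
  dat <- c(list(age_yr = data$age_yr, mass_kg = data$mass_kg), fixed)
  rhs <- "w_inf * (1 - exp(-k * (age_yr - t0)))^b"
  form <- stats::as.formula(
    if (log_mass) paste("log(mass_kg) ~ log(", rhs, ")")
    else paste("mass_kg ~", rhs)
  )
  fit <- stats::nls(form, data = dat,
                    start = start, lower = lower, upper = upper,
                    algorithm = "port",
                    control = stats::nls.control(maxiter = 200))
  coefs <- summary(fit)$coefficients
  est <- data.frame(parameter = rownames(coefs),
                    estimate = coefs[, "Estimate"],
                    se = coefs[, "Std. Error"],
                    row.names = NULL)
  get_par <- function(nm) {
    if (nm %in% names(fixed)) fixed[[nm]] else unname(stats::coef(fit)[nm])
  }
  params <- growth_params(w_inf = get_par("w_inf"), k = get_par("k"),
                          t0 = get_par("t0"), b = get_par("b"), a = a)
  list(params = params, estimates = est, fit = fit,
       residuals = stats::residuals(fit))
}
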