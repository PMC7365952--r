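#' Cardinal temperatures of a microbial growth phase
#'
#' Bundles the minimum, optimum and maximum temperatures of the cardinal
#' temperature model with inflection (CTMI) that scales the substrate
#' degradation rate between 0 and 1.
#'
#' @param t_min Minimum temperature (degrees C) below which activity stops.
#' @param t_opt Optimum temperature (degrees C) at which the factor equals 1.
#' @param t_max Maximum temperature (degrees C) above which activity stops.
#'
#' @return An object of class `cardinal_temperatures`.
#' @seealso [temperature_factor()]
#' @examples
#' cardinal_temperatures(4.4, 46.7, 73.6)
#' @export
cardinal_temperatures <- function(t_min, t_opt, t_max) {
  stopifnot(is.numeric(t_min), is.numeric(t_opt), is.numeric(t_max),
            length(t_min) == 1, length(t_opt) == 1, length(t_max) == 1)
  if (!(t_min < t_opt && t_opt < t_max)) {
    stop("cardinal temperatures must satisfy t_min < t_opt < t_max (got ",
         t_min, ", ", t_opt, ", ", t_max, ")", call. = FALSE)
  }
  structure(list(t_min = t_min, t_opt = t_opt, t_max = t_max),
            class = "cardinal_temperatures")
}

#' @export
print.cardinal_temperatures <- function(x, ...) {
  cat(sprintf("<cardinal temperatures> t_min = %g, t_opt = %g, t_max = %g degC\n",
              x$t_min, x$t_opt, x$t_max))
  invisible(x)
}

#' Dimensionless CTMI temperature factor
#'
#' Evaluates the cardinal temperature model with inflection: a dimensionless
#' multiplier on the substrate decay rate that equals 1 at the optimum
#' temperature and 0 at (and beyond) the cardinal extremes. Outside the
#' interval `[t_min, t_max]` the raw rational expression can become negative
#' or undefined, so the factor is clamped to 0 there and clipped to `[0, 1]`
#' inside, which is standard CTMI practice.
#'
#' The CTMI shape is smooth and monotone on the suboptimal side only when
#' the optimum lies in the upper half of the cardinal range
#' (`t_opt - t_min > t_max - t_opt`), as it does for every parameter set
#' reported for this system; outside that region the rational expression
#' has a pole below the optimum and the clip merely keeps the factor
#' bounded in `[0, 1]`.
#'
#' @param t Temperature(s), degrees C. Vectorized.
#' @param cardinals A [cardinal_temperatures()] object.
#'
#' @return Numeric vector in `[0, 1]`, same length as `t`.
#' @examples
#' temperature_factor(25, cardinal_temperatures(5.1, 38.5, 63.6))
#' @export
temperature_factor <- function(t, cardinals) {
  stopifnot(inherits(cardinals, "cardinal_temperatures"), is.numeric(t))
  tmin <- cardinals$t_min; topt <- cardinals$t_opt; tmax <- cardinals$t_max
  num <- (t - tmax) * (t - tmin)^2
  den <- (topt - tmin) *
    ((topt - tmin) * (t - topt) - (topt - tmax) * (topt + tmin - 2 * t))
  f <- num / den
  f[t <= tmin | t >= tmax] <- 0
  pmin(pmax(f, 0), 1)
}

#' Dimensionless Monod moisture factor
#'
#' Half-saturation form `m / (m_half + m)` on wet-basis moisture content
#' expressed as a fraction (0.30, not 30). The default half-saturation
#' constant 0.25 corresponds to the moisture content at half the maximum
#' specific growth rate.
#'
#' @param m Wet-basis moisture fraction(s), `>= 0`. Vectorized.
#' @param m_half Half-saturation moisture fraction (`> 0`), default 0.25.
#'
#' @return Numeric vector in `[0, 1)`.
#' @examples
#' moisture_factor(0.25)       # 0.5 by construction
#' moisture_factor(0.30, 0.25)
#' @export
moisture_factor <- function(m, m_half = 0.25) {
  stopifnot(is.numeric(m), is.numeric(m_half), length(m_half) == 1, m_half > 0)
  if (any(m < 0)) stop("moisture fraction must be >= 0", call. = FALSE)
  m / (m_half + m)
}

#' Linear drying schedule of the stored biomass
#'
#' The reactors dry monotonically from an initial to a final wet-basis
#' moisture content over the storage period; moisture is interpolated
#' linearly in time and clamped at the final value beyond the configured
#' duration.
#'
#' @param m_initial,m_final Wet-basis moisture fractions in (0, 1).
#' @param duration_days Storage duration in days (> 0).
#' @param m_half Half-saturation moisture fraction forwarded to
#'   [moisture_factor()], default 0.25.
#'
#' @return An object of class `moisture_model`.
#' @examples
#' moisture_model(0.2986, 0.1693, 34.1)
#' @export
moisture_model <- function(m_initial, m_final, duration_days, m_half = 0.25) {
  stopifnot(is.numeric(m_initial), is.numeric(m_final), is.numeric(duration_days))
  if (m_initial <= 0 || m_initial >= 1 || m_final <= 0 || m_final >= 1)
    stop("moisture fractions must lie in (0, 1) wet basis", call. = FALSE)
  if (duration_days <= 0) stop("duration_days must be > 0", call. = FALSE)
  if (m_half <= 0) stop("m_half must be > 0", call. = FALSE)
  structure(list(m_initial = m_initial, m_final = m_final,
                 duration_days = duration_days, m_half = m_half),
            class = "moisture_model")
}

#' Moisture content at a given storage time
#'
#' @param t_days Time(s) since loading, days (`>= 0`). Vectorized.
#' @param model A [moisture_model()].
#'
#' @return Wet-basis moisture fraction(s).
#' @examples
#' moisture_at(17.05, moisture_model(0.2986, 0.1693, 34.1))
#' @export
moisture_at <- function(t_days, model) {
  stopifnot(inherits(model, "moisture_model"), is.numeric(t_days))
  if (any(t_days < 0)) stop("t_days must be >= 0", call. = FALSE)
  frac <- pmin(t_days / model$duration_days, 1)
  model$m_initial + (model$m_final - model$m_initial) * frac
}

#' One phase of the bi-phasic degradation model
#'
#' A growth phase owns a degradable substrate pool (a fraction of the total
#' pool), a first-order specific degradation rate, its own cardinal
#' temperatures, and a lag time before which the phase is inert.
#'
#' @param cardinals A [cardinal_temperatures()] object.
#' @param k_d Specific degradation rate, 1/s (`>= 0`).
#' @param pool_fraction Fraction of the total degradable pool owned by this
#'   phase, in `[0, 1]`.
#' @param lag_days Lag before the phase becomes active, days (`>= 0`).
#'
#' @return An object of class `growth_phase`.
#' @examples
#' growth_phase(cardinal_temperatures(4.4, 46.7, 73.6), k_d = 7.6e-6,
#'              pool_fraction = 0.501)
#' @export
growth_phase <- function(cardinals, k_d, pool_fraction = 1, lag_days = 0) {
  stopifnot(inherits(cardinals, "cardinal_temperatures"))
  if (k_d < 0) stop("k_d must be >= 0", call. = FALSE)
  if (pool_fraction < 0 || pool_fraction > 1)
    stop("pool_fraction must lie in [0, 1]", call. = FALSE)
  if (lag_days < 0) stop("lag_days must be >= 0", call. = FALSE)
  structure(list(cardinals = cardinals, k_d = k_d,
                 pool_fraction = pool_fraction, lag_days = lag_days),
            class = "growth_phase")
}

# Validates a list of growth phases: pool fractions must sum to 1.
validate_phases <- function(phases) {
  if (inherits(phases, "growth_phase")) phases <- list(phases)
  stopifnot(length(phases) >= 1)
  ok <- vapply(phases, inherits, logical(1), what = "growth_phase")
  if (!all(ok)) stop("phases must be growth_phase objects", call. = FALSE)
  total <- sum(vapply(phases, `[[`, numeric(1), "pool_fraction"))
  if (abs(total - 1) > 1e-9)
    stop("pool fractions must sum to 1 (got ", format(total), ")", call. = FALSE)
  phases
}

#' Conversion yields from substrate to CO2 and microbial heat
#'
#' Cumulative CO2 mass and microbial heat are strictly proportional to the
#' cumulative substrate degraded. The default CO2 yield 1.44 g/g is the
#' experimentally determined conversion coefficient; the default heat yield
#' 9.7 J/g is the calibrated heat evolution per unit substrate degraded.
#'
#' @param y_co2 g CO2 released per g substrate degraded (`>= 0`).
#' @param y_m J of microbial heat per g substrate degraded (`>= 0`).
#'
#' @return An object of class `yield_coefficients`.
#' @export
yield_coefficients <- function(y_co2 = 1.44, y_m = 9.7) {
  if (y_co2 < 0 || y_m < 0) stop("yields must be >= 0", call. = FALSE)
  structure(list(y_co2 = y_co2, y_m = y_m), class = "yield_coefficients")
}

#' Per-phase substrate degradation rates
#'
#' First-order kinetics on the remaining pool of each phase, modulated by the
#' shared environmental factors: `rate_i = k_d_i * f(T)_i * f(M) * (s0_i -
#' s_deg_i)`, zero while the phase is still in its lag and zero once its pool
#' is exhausted.
#'
#' @param t_days Current time, days.
#' @param state List with numeric vectors `s_deg` (mass degraded so far, g)
#'   and `s0` (pool sizes, g), one element per phase.
#' @param temp_c Current biomass temperature, degrees C.
#' @param moisture Current wet-basis moisture fraction.
#' @param phases List of [growth_phase()] objects (or a single one).
#' @param m_half Half-saturation moisture fraction, default 0.25.
#'
#' @return Numeric vector of degradation rates, g/s, one per phase.
#' @export
substrate_rates <- function(t_days, state, temp_c, moisture, phases,
                            m_half = 0.25) {
  phases <- validate_phases(phases)
  s_deg <- state$s_deg; s0 <- state$s0
  stopifnot(length(s_deg) == length(phases), length(s0) == length(phases))
  if (any(s_deg < 0) || any(s_deg > s0 + 1e-9 * pmax(s0, 1)))
    stop("s_deg must satisfy 0 <= s_deg <= s0 per phase", call. = FALSE)
  fm <- moisture_factor(moisture, m_half)
  vapply(seq_along(phases), function(i) {
    ph <- phases[[i]]
    if (t_days < ph$lag_days) return(0)
    remaining <- max(s0[i] - s_deg[i], 0)
    ph$k_d * temperature_factor(temp_c, ph$cardinals) * fm * remaining
  }, numeric(1))
}

#' CO2 and microbial heat production rates
#'
#' Both by-products are proportional to the total substrate degradation
#' rate.
#'
#' @param rate_total Total substrate degradation rate, g/s (`>= 0`).
#' @param yields A [yield_coefficients()] object.
#'
#' @return A list with `co2_rate` (g CO2 per s) and `heat` (W).
#' @export
byproduct_rates <- function(rate_total, yields) {
  stopifnot(inherits(yields, "yield_coefficients"))
  if (any(rate_total < 0)) stop("rate_total must be >= 0", call. = FALSE)
  list(co2_rate = yields$y_co2 * rate_total, heat = yields$y_m * rate_total)
}
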