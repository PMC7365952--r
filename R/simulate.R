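#' Operating configuration of a storage reactor
#'
#' The deterministic model inputs of one reactor run: initial and ambient
#' temperatures, loading dry matter, airflow, the linear drying schedule and
#' the storage duration, plus two derived-quantity settings (the airflow
#' cross-section used to convert volumetric airflow to a velocity, and the
#' degradable-pool fraction that sizes the total substrate pool as a
#' fraction of loading dry matter).
#'
#' @param t_initial Initial biomass temperature, degrees C.
#' @param t_ambient Ambient air temperature, degrees C.
#' @param loading_dry_matter Loading dry matter, g.
#' @param airflow Aeration rate, cm3/min.
#' @param moisture A [moisture_model()] describing the drying schedule.
#' @param duration_days Storage duration, days.
#' @param cross_section Flow cross-section for the air-velocity estimate, m2.
#' @param s0_fraction Total degradable pool as a fraction of loading dry
#'   matter (default 0.05, consistent with the ~5% dry matter losses these
#'   reactors exhibit).
#'
#' @return An object of class `reactor_config`.
#' @examples
#' reactor_config(12.9, 24.3, 7080, 347, moisture_model(0.2986, 0.1693, 34.1),
#'                34.1)
#' @export
reactor_config <- function(t_initial, t_ambient, loading_dry_matter, airflow,
                           moisture, duration_days, cross_section = 0.07,
                           s0_fraction = 0.05) {
  stopifnot(inherits(moisture, "moisture_model"))
  if (loading_dry_matter <= 0) stop("loading_dry_matter must be > 0", call. = FALSE)
  if (airflow < 0) stop("airflow must be >= 0", call. = FALSE)
  if (duration_days <= 0) stop("duration_days must be > 0", call. = FALSE)
  if (cross_section <= 0) stop("cross_section must be > 0", call. = FALSE)
  if (s0_fraction <= 0 || s0_fraction > 1)
    stop("s0_fraction must lie in (0, 1]", call. = FALSE)
  structure(list(t_initial = t_initial, t_ambient = t_ambient,
                 loading_dry_matter = loading_dry_matter, airflow = airflow,
                 moisture = moisture, duration_days = duration_days,
                 cross_section = cross_section, s0_fraction = s0_fraction),
            class = "reactor_config")
}

#' @export
print.reactor_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<reactor config> T0 = %g degC, Tamb = %g degC, dry matter = %g g,\n",
    "  airflow = %g cm3/min, moisture %.4f -> %.4f over %g d, S0 = %.1f g\n"),
    x$t_initial, x$t_ambient, x$loading_dry_matter, x$airflow,
    x$moisture$m_initial, x$moisture$m_final, x$duration_days,
    x$s0_fraction * x$loading_dry_matter))
  invisible(x)
}

#' Integrator settings for the forward simulation
#'
#' @param rel_tol,abs_tol Relative/absolute tolerances of the adaptive
#'   Dormand-Prince stepper.
#' @param max_step Maximum internal step, s.
#' @param output_interval Output grid spacing, s (default 300 s, the
#'   thermocouple logging cadence).
#' @param output_times Optional explicit output time grid, s; overrides
#'   `output_interval`.
#' @param fixed_step When set, integrate with classical fixed-step RK4 on a
#'   grid of this spacing (s) instead of the adaptive stepper. A fixed grid
#'   makes the discretization error a smooth function of the model
#'   parameters, which keeps finite-difference sensitivities clean during
#'   calibration; the adaptive stepper remains the default for forward
#'   simulation.
#'
#' @return An object of class `solver_options`.
#' @export
solver_options <- function(rel_tol = 1e-6, abs_tol = 1e-8, max_step = 3600,
                           output_interval = 300, output_times = NULL,
                           fixed_step = NULL) {
  if (rel_tol <= 0 || abs_tol <= 0) stop("tolerances must be > 0", call. = FALSE)
  if (output_interval <= 0) stop("output_interval must be > 0", call. = FALSE)
  if (!is.null(fixed_step) && fixed_step <= 0)
    stop("fixed_step must be > 0", call. = FALSE)
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol, max_step = max_step,
                 output_interval = output_interval,
                 output_times = output_times, fixed_step = fixed_step),
            class = "solver_options")
}

# Validates an observed forcing series (tibble/data.frame with a strictly
# increasing time_days column) and returns it as a plain data.frame.
check_forcing_series <- function(x, value_col, what) {
  if (!is.data.frame(x) || !all(c("time_days", value_col) %in% names(x)))
    stop(what, " series must be a data frame with columns time_days and ",
         value_col, call. = FALSE)
  if (nrow(x) < 1) stop(what, " series is empty", call. = FALSE)
  if (is.unsorted(x$time_days, strictly = TRUE))
    stop(what, " series time_days must be strictly increasing", call. = FALSE)
  as.data.frame(x)[, c("time_days", value_col)]
}

# Assembles the ODE right-hand side and initial state for one reactor run.
# The closure is written for speed (it is evaluated ~10^4 times per
# simulation and ~10^6 times during calibration): all constants are resolved
# up front and the body is plain arithmetic.
build_reactor_ode <- function(config, phases, yields, thermal, controller,
                              air, jacket_series = NULL,
                              condensate_series = NULL,
                              capacitance_mode = "loaded_mass") {
  phases <- validate_phases(phases)
  n <- length(phases)
  dur_s <- config$duration_days * 86400

  s0 <- config$s0_fraction * config$loading_dry_matter *
    vapply(phases, `[[`, numeric(1), "pool_fraction")
  kd <- vapply(phases, `[[`, numeric(1), "k_d")
  tmin <- vapply(phases, function(p) p$cardinals$t_min, numeric(1))
  topt <- vapply(phases, function(p) p$cardinals$t_opt, numeric(1))
  tmax <- vapply(phases, function(p) p$cardinals$t_max, numeric(1))
  lag_s <- vapply(phases, `[[`, numeric(1), "lag_days") * 86400

  mo <- config$moisture
  mi <- mo$m_initial; mf <- mo$m_final
  mdur_s <- mo$duration_days * 86400; mhalf <- mo$m_half

  kLA <- thermal$k_cond / thermal$length * thermal$area
  u <- config$airflow * 1e-6 / 60 / config$cross_section
  h <- if (!is.null(thermal$h_conv_override)) thermal$h_conv_override
       else convective_coefficient(air, u, thermal$length)
  hA <- h * thermal$area
  tamb <- config$t_ambient
  ym <- yields$y_m

  thr <- controller$activation_threshold
  off <- controller$offset
  flo <- controller$floor_temperature
  if (!is.null(jacket_series)) {
    js <- check_forcing_series(jacket_series, "jacket_temp_C", "jacket")
    jfun <- stats::approxfun(js$time_days * 86400, js$jacket_temp_C, rule = 2)
    jacket_at <- function(t, T) jfun(t)
  } else {
    jacket_at <- function(t, T) if (T > thr) T + off else flo
  }

  if (!is.null(condensate_series)) {
    cs <- check_forcing_series(condensate_series, "condensate_kg", "condensate")
    if (any(cs$condensate_kg < 0))
      stop("condensate volumes must be >= 0", call. = FALSE)
    # daily collected volumes -> piecewise-constant removal rate over the
    # interval ending at each sample time
    t_end <- cs$time_days * 86400
    t_start <- c(0, t_end[-length(t_end)])
    rate <- cs$condensate_kg / pmax(t_end - t_start, 1)
    efun <- stats::approxfun(t_start, rate, method = "constant", rule = 2)
    evap_w_at <- function(t) -thermal$h_vap * 1000 * efun(t)
  } else {
    e0 <- -thermal$h_vap * 1000 * default_evaporation_rate(mo, config$loading_dry_matter)
    evap_w_at <- function(t) e0
  }

  dm_kg <- config$loading_dry_matter / 1000
  ss_term <- thermal$rho_ss * thermal$v_ss * thermal$c_ss
  fixed_mass <- if (capacitance_mode == "density_volume") {
    bio <- biomass_properties(config$loading_dry_matter,
                              capacitance_mode = "density_volume")
    bio$bulk_density * bio$volume
  } else NULL

  rhs <- function(t, y, parms) {
    T <- y[1]
    s <- y[-1]
    m <- if (t >= mdur_s) mf else mi + (mf - mi) * (t / mdur_s)
    fm <- m / (mhalf + m)

    ft <- (T - tmax) * (T - tmin)^2 /
      ((topt - tmin) * ((topt - tmin) * (T - topt) -
                          (topt - tmax) * (topt + tmin - 2 * T)))
    ft[T <= tmin | T >= tmax] <- 0
    ft[ft < 0] <- 0
    ft[ft > 1] <- 1

    # parms carries the per-segment phase-activity mask (integration is
    # restarted at each lag onset, so activity is constant within a segment)
    act <- if (is.null(parms)) as.numeric(t >= lag_s) else parms
    rate <- kd * ft * fm * pmax(s0 - s, 0) * act

    tk <- T + 273.15
    cwet <- (0.1031 + 0.00386 * tk + 4.19 * m) / (1 + m) +
      (0.02355 * tk - 1.32 * m - 6.191) * m
    mass <- if (is.null(fixed_mass)) dm_kg / (1 - m) else fixed_mass
    cth <- mass * cwet * 1000 + ss_term

    q <- ym * sum(rate) + kLA * (jacket_at(t, T) - T) + hA * (tamb - T) +
      evap_w_at(t)
    list(c(q / cth, rate))
  }

  list(rhs = rhs, y0 = c(config$t_initial, rep(0, n)), dur_s = dur_s,
       lag_s = lag_s, s0 = s0, h = h, n_phases = n,
       jacket_at = jacket_at, evap_w_at = evap_w_at)
}

#' Simulate a storage reactor run
#'
#' Integrates the coupled state vector (biomass temperature plus per-phase
#' cumulative substrate degraded) with an adaptive Dormand-Prince 4(5)
#' stepper, restarting the integration at each phase's lag onset so the
#' stepper never straddles that discontinuity. Cumulative CO2 and microbial
#' heat are reconstructed algebraically from the substrate states (they are
#' exactly proportional), and all heat-flow components are reported on the
#' output grid.
#'
#' When a measured jacket temperature series or daily condensate series is
#' supplied it replaces the internal controller / drying-balance model for
#' that term (piecewise-linear interpolation for the jacket, piecewise
#' constant rates for the condensate; constant extrapolation beyond the last
#' sample).
#'
#' @param config A [reactor_config()].
#' @param phases A [growth_phase()] or list of them (pool fractions must sum
#'   to 1).
#' @param yields A [yield_coefficients()].
#' @param thermal A [thermal_params()].
#' @param controller A [jacket_controller()].
#' @param air An [air_properties()].
#' @param solver A [solver_options()].
#' @param jacket_series Optional data frame with `time_days`,
#'   `jacket_temp_C`.
#' @param condensate_series Optional data frame with `time_days`,
#'   `condensate_kg` (mass collected over the interval ending at each time).
#' @param capacitance_mode `"loaded_mass"` (default) or `"density_volume"`;
#'   see [biomass_properties()].
#'
#' @return An object of class `stover_simulation`; its `$series` element is
#'   a tibble with one row per output time carrying the temperature, the
#'   per-phase substrate states, cumulative CO2 and microbial heat, the four
#'   heat-flow components, the environmental factors and the thermal
#'   capacitance.
#' @examples
#' cfg <- reactor_config(12.9, 24.3, 7080, 347,
#'                       moisture_model(0.2986, 0.1693, 34.1), 2)
#' ph <- growth_phase(cardinal_temperatures(4.4, 46.7, 73.6), 7.6e-6)
#' sim <- simulate_reactor(cfg, ph, solver = solver_options(output_interval = 3600))
#' dry_matter_loss(sim)
#' @export
simulate_reactor <- function(config, phases, yields = yield_coefficients(),
                             thermal = thermal_params(),
                             controller = jacket_controller(),
                             air = air_properties(),
                             solver = solver_options(),
                             jacket_series = NULL, condensate_series = NULL,
                             capacitance_mode = c("loaded_mass",
                                                  "density_volume")) {
  stopifnot(inherits(config, "reactor_config"),
            inherits(yields, "yield_coefficients"),
            inherits(thermal, "thermal_params"),
            inherits(controller, "jacket_controller"),
            inherits(air, "air_properties"),
            inherits(solver, "solver_options"))
  capacitance_mode <- match.arg(capacitance_mode)
  if (inherits(phases, "growth_phase")) phases <- list(phases)

  sys <- build_reactor_ode(config, phases, yields, thermal, controller, air,
                           jacket_series, condensate_series, capacitance_mode)
  dur_s <- sys$dur_s

  out_times <- if (!is.null(solver$output_times)) {
    tt <- sort(unique(c(0, solver$output_times, dur_s)))
    tt[tt >= 0 & tt <= dur_s]
  } else {
    sort(unique(c(seq(0, dur_s, by = solver$output_interval), dur_s)))
  }
  boundaries <- sort(unique(sys$lag_s[sys$lag_s > 0 & sys$lag_s < dur_s]))
  segments <- cbind(c(0, boundaries), c(boundaries, dur_s))

  y <- sys$y0
  rows <- vector("list", nrow(segments))
  for (i in seq_len(nrow(segments))) {
    a <- segments[i, 1]; b <- segments[i, 2]
    active <- as.numeric(a >= sys$lag_s - 1e-9)
    tt <- sort(unique(c(a, out_times[out_times > a & out_times < b], b)))
    if (is.null(solver$fixed_step)) {
      sol <- deSolve::ode(y = y, times = tt, func = sys$rhs, parms = active,
                          method = "ode45", rtol = solver$rel_tol,
                          atol = solver$abs_tol,
                          hmax = if (is.null(solver$max_step)) b - a
                                 else solver$max_step)
    } else {
      grid <- sort(unique(c(seq(a, b, by = solver$fixed_step), tt)))
      sol <- deSolve::ode(y = y, times = grid, func = sys$rhs, parms = active,
                          method = "rk4")
      sol <- sol[sol[, 1] %in% tt, , drop = FALSE]
    }
    sol <- unclass(sol)
    y <- as.numeric(sol[nrow(sol), -1])
    keep <- sol[, 1] %in% out_times
    if (i > 1) keep[1] <- FALSE  # boundary row already emitted
    rows[[i]] <- sol[keep, , drop = FALSE]
  }
  sol <- do.call(rbind, rows)

  n <- sys$n_phases
  time_s <- sol[, 1]
  temp <- sol[, 2]
  s_deg <- sol[, 3:(2 + n), drop = FALSE]
  s_total <- rowSums(s_deg)

  m <- moisture_at(pmin(time_s / 86400, config$moisture$duration_days),
                   config$moisture)
  fm <- moisture_factor(m, config$moisture$m_half)
  jt <- vapply(seq_along(time_s),
               function(i) sys$jacket_at(time_s[i], temp[i]), numeric(1))
  e_w <- vapply(time_s, sys$evap_w_at, numeric(1))

  rate_mat <- matrix(0, length(time_s), n)
  ft_mat <- matrix(0, length(time_s), n)
  for (j in seq_len(n)) {
    ft_mat[, j] <- temperature_factor(temp, phases[[j]]$cardinals)
    active <- time_s >= phases[[j]]$lag_days * 86400
    rate_mat[, j] <- phases[[j]]$k_d * ft_mat[, j] * fm *
      pmax(sys$s0[j] - s_deg[, j], 0) * active
  }
  q_m <- yields$y_m * rowSums(rate_mat)
  q_k <- (thermal$k_cond / thermal$length) * thermal$area * (jt - temp)
  q_h <- sys$h * thermal$area * (config$t_ambient - temp)

  bio <- biomass_properties(config$loading_dry_matter,
                            capacitance_mode = capacitance_mode)
  c_th <- thermal_capacitance(bio, thermal, temp + 273.15, m)

  series <- tibble::tibble(
    time_s = time_s,
    time_days = time_s / 86400,
    temperature_C = temp,
    jacket_temp_C = jt,
    moisture = m,
    f_moisture = fm)
  for (j in seq_len(n)) {
    series[[paste0("f_temperature_", j)]] <- ft_mat[, j]
    series[[paste0("s_deg_", j)]] <- s_deg[, j]
  }
  series$s_deg_total <- s_total
  series$co2_g <- yields$y_co2 * s_total
  series$heat_microbial_J <- yields$y_m * s_total
  series$q_microbial_W <- q_m
  series$q_conduction_W <- q_k
  series$q_convection_W <- q_h
  series$q_evaporation_W <- e_w
  series$q_net_W <- q_m + q_k + q_h + e_w
  series$c_th_J_K <- c_th

  structure(list(series = series, config = config, phases = phases,
                 yields = yields, thermal = thermal, controller = controller,
                 air = air, solver = solver, h_coefficient = sys$h,
                 s0 = sys$s0, capacitance_mode = capacitance_mode),
            class = "stover_simulation")
}

#' @export
print.stover_simulation <- function(x, ...) {
  s <- x$series
  cat(sprintf(paste0(
    "<stover storage simulation> %d phases, %.1f days, %d output points\n",
    "  final temperature %.2f degC, substrate degraded %.1f g (DML %.2f%%)\n"),
    length(x$phases), x$config$duration_days, nrow(s),
    s$temperature_C[nrow(s)], s$s_deg_total[nrow(s)], dry_matter_loss(x)))
  invisible(x)
}

#' Dry matter loss of a simulated run
#'
#' Cumulative substrate degraded at the end of the run as a percentage of
#' the loading dry matter.
#'
#' @param result A `stover_simulation` from [simulate_reactor()].
#' @param loading_dm Loading dry matter, g; defaults to the value in the
#'   simulation's configuration.
#'
#' @return Dry matter loss, percent.
#' @export
dry_matter_loss <- function(result, loading_dm = result$config$loading_dry_matter) {
  stopifnot(inherits(result, "stover_simulation"), loading_dm > 0)
  100 * result$series$s_deg_total[nrow(result$series)] / loading_dm
}
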