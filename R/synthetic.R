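#' Measurement-noise specification for synthetic datasets
#'
#' Additive, independent Gaussian noise per observation channel, emulating
#' RTD temperature-probe and gas-chromatograph measurement error. Every
#' stochastic output is reproducible from the seed.
#'
#' @param sigma_temperature Temperature noise SD, degrees C.
#' @param sigma_substrate Substrate noise SD, g (absolute). Ignored when
#'   `sigma_substrate_frac` is set.
#' @param sigma_substrate_frac Substrate noise SD as a fraction of the final
#'   noiseless cumulative substrate (default 0.01).
#' @param sigma_condensate Daily condensate noise SD, kg.
#' @param seed Integer seed.
#'
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sigma_temperature = 0.2, sigma_substrate = NULL,
                       sigma_substrate_frac = 0.01, sigma_condensate = 0,
                       seed = 1L) {
  sig <- c(sigma_temperature, sigma_substrate, sigma_substrate_frac,
           sigma_condensate)
  if (any(sig < 0)) stop("noise sigmas must be >= 0", call. = FALSE)
  structure(list(sigma_temperature = sigma_temperature,
                 sigma_substrate = sigma_substrate,
                 sigma_substrate_frac = sigma_substrate_frac,
                 sigma_condensate = sigma_condensate,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' The four benchmark reactor configurations
#'
#' Operating conditions of the four laboratory storage-reactor replicates:
#' initial and ambient temperatures, loading dry matter, airflow, moisture
#' endpoints and storage duration.
#'
#' @param s0_fraction Degradable-pool fraction forwarded to
#'   [reactor_config()].
#'
#' @return A named list of four [reactor_config()] objects
#'   (`reactor_1` ... `reactor_4`).
#' @examples
#' reactor_fixtures()$reactor_2$loading_dry_matter  # 7080
#' @export
reactor_fixtures <- function(s0_fraction = 0.05) {
  tab <- tibble::tibble(
    reactor    = 1:4,
    t_initial  = c(10.6, 12.9, 13.8, 13.5),
    t_ambient  = c(24.2, 24.3, 24.0, 23.5),
    loading_dm = c(6456, 7080, 7071, 7290),
    airflow    = c(365, 347, 1265, 1209),
    m_initial  = c(0.3086, 0.2986, 0.2899, 0.2915),
    m_final    = c(0.1546, 0.1693, 0.1801, 0.1838),
    duration   = c(34.7, 34.1, 10.7, 10.7))
  out <- purrr::pmap(tab, function(reactor, t_initial, t_ambient, loading_dm,
                                   airflow, m_initial, m_final, duration) {
    reactor_config(t_initial, t_ambient, loading_dm, airflow,
                   moisture_model(m_initial, m_final, duration),
                   duration, s0_fraction = s0_fraction)
  })
  stats::setNames(out, paste0("reactor_", tab$reactor))
}

#' Calibrated bi-phasic growth scenario
#'
#' The two-phase parameter set calibrated on the benchmark reactor: phase 1
#' (cardinals 4.4/46.7/73.6 degrees C, k_d 7.6e-6 1/s) degrades 50.1% of
#' the pool from time zero; phase 2 (cardinals 5.1/38.5/63.6 degrees C, k_d
#' 8.3e-6 1/s) owns the remaining 49.9% and wakes after an 11.2-day lag.
#' Yields are shared across phases (y_co2 = 1.44 g/g, y_m = 9.7 J/g).
#'
#' @return A list with `phases` (list of two [growth_phase()]) and `yields`
#'   (a [yield_coefficients()]).
#' @export
biphasic_scenario <- function() {
  list(
    phases = list(
      growth_phase(cardinal_temperatures(4.4, 46.7, 73.6), k_d = 7.6e-6,
                   pool_fraction = 0.501, lag_days = 0),
      growth_phase(cardinal_temperatures(5.1, 38.5, 63.6), k_d = 8.3e-6,
                   pool_fraction = 0.499, lag_days = 11.2)),
    yields = yield_coefficients(y_co2 = 1.44, y_m = 9.7))
}

# Smooth jacket temperature program emulating the experimental campaign:
# holds the controller floor at loading, rises as a gamma pulse to a peak
# and decays back toward the floor.
jacket_program <- function(t_days, floor = 20, peak = 40, peak_day = 8,
                           shape = 2) {
  pulse <- (t_days / peak_day)^shape * exp(shape * (1 - t_days / peak_day))
  floor + (peak - floor) * pulse
}

#' Generate a reactor-like observation set with known ground truth
#'
#' Runs the forward model and samples it on realistic measurement grids
#' (temperature every 5 min, CO2-derived substrate hourly, condensate
#' daily), adding independent Gaussian noise per channel. Two jacket modes
#' are available: `"driven"` (default) synthesizes a smooth jacket
#' temperature program that rises from the controller floor to ~40 degrees C
#' and decays, emulating the thermal trajectory of the experimental
#' campaign, and supplies it to the simulator as a measured series;
#' `"controller"` uses the closed-loop jacket model instead.
#'
#' @param config A [reactor_config()].
#' @param phases Growth phase(s); defaults to the calibrated bi-phasic set.
#' @param yields,thermal,controller,air,solver Model objects as in
#'   [simulate_reactor()].
#' @param noise A [noise_spec()].
#' @param jacket_mode `"driven"` or `"controller"`.
#' @param jacket_peak,jacket_peak_day Peak temperature (degrees C) and peak
#'   time (days) of the driven jacket program.
#'
#' @return An object of class `stover_dataset`: a list with `observed` (a
#'   wide tibble with columns `time_days`, `stover_temp_C`, `substrate_g`,
#'   `jacket_temp_C`, `condensate_kg`, `NA` where a channel was not
#'   sampled), `truth` (the generating parameter objects), `sim` (the
#'   noiseless forward simulation) and `noise`.
#' @export
generate_dataset <- function(config, phases = biphasic_scenario()$phases,
                             yields = biphasic_scenario()$yields,
                             thermal = thermal_params(),
                             controller = jacket_controller(),
                             air = air_properties(),
                             solver = solver_options(),
                             noise = noise_spec(),
                             jacket_mode = c("driven", "controller"),
                             jacket_peak = 40, jacket_peak_day = 8) {
  stopifnot(inherits(noise, "noise_spec"))
  jacket_mode <- match.arg(jacket_mode)

  dur_s <- config$duration_days * 86400
  jacket_series <- NULL
  if (jacket_mode == "driven") {
    jt <- seq(0, dur_s, by = 3600) / 86400
    jacket_series <- tibble::tibble(
      time_days = jt,
      jacket_temp_C = jacket_program(jt, floor = controller$floor_temperature,
                                     peak = jacket_peak,
                                     peak_day = jacket_peak_day))
  }

  # grids built in integer seconds so coincident sample times join exactly
  t_temp <- seq(0, dur_s, by = 300) / 86400
  t_sub <- seq(0, dur_s, by = 3600) / 86400
  t_cond <- seq(86400, floor(config$duration_days) * 86400, by = 86400) / 86400
  solver$output_times <- sort(unique(c(t_temp, t_sub, t_cond))) * 86400

  sim <- simulate_reactor(config, phases, yields, thermal, controller, air,
                          solver, jacket_series = jacket_series)
  s <- sim$series

  at <- function(times, col) {
    stats::approx(s$time_days, s[[col]], xout = times, rule = 2)$y
  }
  temp_true <- at(t_temp, "temperature_C")
  sub_true <- at(t_sub, "s_deg_total")
  jack_true <- at(t_temp, "jacket_temp_C")
  evap_w <- at(t_cond - 0.5, "q_evaporation_W")
  cond_true <- -evap_w / (thermal$h_vap * 1000) * 86400

  sigma_sub <- noise$sigma_substrate %||%
    (noise$sigma_substrate_frac * sub_true[length(sub_true)])

  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(noise$seed)
  temp_obs <- temp_true + stats::rnorm(length(temp_true), 0,
                                       noise$sigma_temperature)
  sub_obs <- pmax(sub_true + stats::rnorm(length(sub_true), 0, sigma_sub), 0)
  cond_obs <- pmax(cond_true + stats::rnorm(length(cond_true), 0,
                                            noise$sigma_condensate), 0)

  observed <- dplyr::full_join(
    dplyr::full_join(
      tibble::tibble(time_days = t_temp, stover_temp_C = temp_obs,
                     jacket_temp_C = jack_true),
      tibble::tibble(time_days = t_sub, substrate_g = sub_obs),
      by = "time_days"),
    tibble::tibble(time_days = t_cond, condensate_kg = cond_obs),
    by = "time_days")
  observed <- observed[order(observed$time_days), ]

  structure(list(
    observed = observed,
    truth = list(config = config, phases = phases, yields = yields,
                 thermal = thermal, controller = controller),
    sim = sim, noise = noise, jacket_mode = jacket_mode),
    class = "stover_dataset")
}

#' @export
print.stover_dataset <- function(x, ...) {
  cat(sprintf(paste0(
    "<synthetic storage dataset> %.1f days, jacket mode '%s', seed %d\n",
    "  %d temperature, %d substrate, %d condensate samples\n"),
    x$truth$config$duration_days, x$jacket_mode, x$noise$seed,
    sum(!is.na(x$observed$stover_temp_C)),
    sum(!is.na(x$observed$substrate_g)),
    sum(!is.na(x$observed$condensate_kg))))
  invisible(x)
}
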