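#' Off-gas CO2 to cumulative substrate degraded
#'
#' Converts a measured off-gas CO2 volume-fraction series into the
#' cumulative mass of substrate degraded, assuming glucose oxidation:
#' baseline-subtract the ambient CO2 fraction, convert the net volumetric
#' CO2 flow to a mass flow with the ideal gas law (44.01 g/mol), integrate
#' with the trapezoid rule, and divide by the CO2 yield.
#'
#' @param time_days Sample times, days (strictly increasing).
#' @param co2_fraction Off-gas CO2 volume fractions in `[0, 1]`.
#' @param airflow Aeration rate, cm3/min (at `temperature_k`/`pressure_pa`).
#' @param ambient_co2 Ambient CO2 volume fraction subtracted as baseline.
#' @param temperature_k Gas metering temperature, K.
#' @param pressure_pa Gas metering pressure, Pa.
#' @param y_co2 CO2 yield, g CO2 per g substrate.
#'
#' @return A tibble with `time_days`, cumulative `co2_g` and cumulative
#'   `substrate_g`.
#' @export
substrate_from_offgas <- function(time_days, co2_fraction, airflow,
                                  ambient_co2 = 410e-6,
                                  temperature_k = 298.15,
                                  pressure_pa = 101325, y_co2 = 1.44) {
  stopifnot(length(time_days) == length(co2_fraction), length(time_days) >= 1)
  if (is.unsorted(time_days, strictly = TRUE))
    stop("time_days must be strictly increasing", call. = FALSE)
  if (any(co2_fraction < 0 | co2_fraction > 1))
    stop("co2_fraction values must lie in [0, 1]", call. = FALSE)
  net <- co2_fraction - ambient_co2
  if (any(net < 0)) {
    warning("negative net CO2 fractions clipped to 0 (",
            sum(net < 0), " samples)", call. = FALSE)
    net <- pmax(net, 0)
  }
  # net volumetric CO2 flow (m3/s) -> molar -> mass flow (g/s)
  q_m3_s <- airflow * 1e-6 / 60 * net
  mass_rate <- pressure_pa * q_m3_s / (8.314462618 * temperature_k) * 44.01
  dt_s <- diff(time_days) * 86400
  co2_g <- c(0, cumsum((mass_rate[-1] + mass_rate[-length(mass_rate)]) / 2 * dt_s))
  tibble::tibble(time_days = time_days, co2_g = co2_g,
                 substrate_g = co2_g / y_co2)
}

#' Mean absolute error between a model and an observed series
#'
#' `(1/n) * sum |model_i - observed_i|`. Note the convention in this
#' literature labels this quantity a "mean absolute relative error" even
#' though no normalization is applied; the unnormalized formula is what is
#' implemented (the result carries the units of the series, degrees C for
#' temperature).
#'
#' @param model_series,observed_series Aligned numeric vectors.
#'
#' @return Mean absolute error (same units as the inputs).
#' @export
mean_absolute_error <- function(model_series, observed_series) {
  if (length(model_series) != length(observed_series))
    stop("series lengths differ (", length(model_series), " vs ",
         length(observed_series), ")", call. = FALSE)
  if (length(model_series) < 1) stop("need at least one point", call. = FALSE)
  mean(abs(model_series - observed_series))
}

#' Relative error of a scalar prediction, percent
#'
#' `100 * |observed - predicted| / observed`, the dry-matter-loss error
#' metric evaluated at quasi-steady state (the final observed time).
#'
#' @param observed Observed value (nonzero).
#' @param predicted Predicted value.
#'
#' @return Relative error, percent.
#' @export
relative_error <- function(observed, predicted) {
  if (any(observed == 0)) stop("observed value must be nonzero", call. = FALSE)
  100 * abs(observed - predicted) / abs(observed)
}

#' Sum-of-squares cost of a residual vector
#'
#' @param residuals Numeric residual vector.
#' @return Scalar sum of squared residuals.
#' @export
cost <- function(residuals) sum(residuals^2)

#' Calibration parameter specifications
#'
#' One row per free parameter: a name, a baseline (starting) value and box
#' bounds. The defaults are the standard calibration box for these
#' reactors: cardinal temperatures, heat yield, degradation rate, thermal
#' conductivity, heat-flux area and stainless-steel volume.
#'
#' Recognized names: `t_opt`, `t_min`, `t_max`, `k_d` (optionally suffixed
#' `_1`, `_2`, ... to target a single phase; unsuffixed applies to every
#' phase), `lag_time_2` (days), `pool_fraction_1`, `y_m`, `y_co2`,
#' `k_cond`, `area`, `v_ss`, `s0_fraction`.
#'
#' @param name,baseline,lower,upper Vectors defining the specs.
#'
#' @return A tibble with columns `name`, `baseline`, `lower`, `upper`.
#' @export
parameter_specs <- function(name, baseline, lower, upper) {
  specs <- tibble::tibble(name = as.character(name), baseline = baseline,
                          lower = lower, upper = upper)
  bad <- specs$lower > specs$baseline | specs$baseline > specs$upper
  if (any(bad))
    stop("baseline outside bounds for: ",
         paste(specs$name[bad], collapse = ", "), call. = FALSE)
  specs
}

#' @rdname parameter_specs
#' @export
default_parameter_specs <- function() {
  parameter_specs(
    name     = c("t_opt", "t_min", "t_max", "y_m", "k_d", "k_cond", "area", "v_ss"),
    baseline = c(41.3,    4.9,     65,      10,    8.9e-6, 9,       0.6,    0.01),
    lower    = c(35,      0,       55,      0,     0,      6,       0.29,   0),
    upper    = c(55,      20,      75,      Inf,   Inf,    14,      0.975,  Inf))
}

# --- bound-honoring reparameterization ------------------------------------
# Classic Levenberg-Marquardt is unconstrained; the optimizer runs in a
# transformed space mapped bijectively onto each parameter's box:
#   (-Inf, Inf)        identity
#   [l, Inf)           x = l + exp(z)
#   (-Inf, u]          x = u - exp(z)
#   [l, u]             scaled logistic
to_unbounded <- function(x, lower, upper) {
  n <- max(length(x), length(lower), length(upper))
  x <- rep_len(x, n); lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  z <- x
  both <- is.finite(lower) & is.finite(upper)
  z[both] <- stats::qlogis(
    pmin(pmax((x[both] - lower[both]) / (upper[both] - lower[both]), 1e-12),
         1 - 1e-12))
  lo <- is.finite(lower) & !is.finite(upper)
  z[lo] <- log(pmax(x[lo] - lower[lo], 1e-300))
  hi <- !is.finite(lower) & is.finite(upper)
  z[hi] <- log(pmax(upper[hi] - x[hi], 1e-300))
  z
}

to_bounded <- function(z, lower, upper) {
  n <- max(length(z), length(lower), length(upper))
  z <- rep_len(z, n); lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  x <- z
  both <- is.finite(lower) & is.finite(upper)
  x[both] <- lower[both] + (upper[both] - lower[both]) * stats::plogis(z[both])
  lo <- is.finite(lower) & !is.finite(upper)
  x[lo] <- lower[lo] + exp(z[lo])
  hi <- !is.finite(lower) & is.finite(upper)
  x[hi] <- upper[hi] - exp(z[hi])
  x
}

# Applies named parameter values onto the model objects. Suffix "_<i>"
# targets phase i; unsuffixed kinetic names apply to all phases.
apply_parameter_values <- function(values, config, phases, yields, thermal) {
  for (nm in names(values)) {
    v <- values[[nm]]
    idx <- NULL
    base <- nm
    if (grepl("_[0-9]+$", nm)) {
      idx <- as.integer(sub(".*_([0-9]+)$", "\\1", nm))
      base <- sub("_[0-9]+$", "", nm)
      if (idx < 1 || idx > length(phases))
        stop("parameter ", nm, " targets a nonexistent phase", call. = FALSE)
    }
    targets <- if (is.null(idx)) seq_along(phases) else idx
    switch(base,
      t_opt = , t_min = , t_max = {
        for (i in targets) {
          cc <- phases[[i]]$cardinals
          cc[[base]] <- v
          phases[[i]]$cardinals <- cardinal_temperatures(cc$t_min, cc$t_opt,
                                                         cc$t_max)
        }
      },
      k_d = for (i in targets) phases[[i]]$k_d <- v,
      lag_time = for (i in targets) phases[[i]]$lag_days <- v,
      pool_fraction = {
        if (length(phases) != 2)
          stop("pool_fraction calibration requires exactly two phases",
               call. = FALSE)
        phases[[idx]]$pool_fraction <- v
        phases[[setdiff(1:2, idx)]]$pool_fraction <- 1 - v
      },
      y_m = yields$y_m <- v,
      y_co2 = yields$y_co2 <- v,
      k_cond = thermal$k_cond <- v,
      area = thermal$area <- v,
      v_ss = thermal$v_ss <- v,
      s0_fraction = config$s0_fraction <- v,
      stop("unknown calibration parameter: ", nm, call. = FALSE))
  }
  list(config = config, phases = phases, yields = yields, thermal = thermal)
}

# Extracts the observation channels from a wide observed table.
split_observed <- function(observed) {
  if (!is.data.frame(observed) || !"time_days" %in% names(observed))
    stop("observed must be a data frame with a time_days column", call. = FALSE)
  if (is.unsorted(observed$time_days, strictly = TRUE))
    stop("observed time_days must be strictly increasing", call. = FALSE)
  pick <- function(col) {
    if (!col %in% names(observed)) return(NULL)
    rows <- !is.na(observed[[col]])
    if (!any(rows)) return(NULL)
    out <- observed[rows, c("time_days", col)]
    if (col %in% c("substrate_g", "condensate_kg") && any(out[[col]] < 0))
      stop("negative values in observed ", col, call. = FALSE)
    out
  }
  list(temperature = pick("stover_temp_C"), substrate = pick("substrate_g"),
       jacket = pick("jacket_temp_C"), condensate = pick("condensate_kg"))
}

#' Weighted residual vector of a parameter set against observations
#'
#' Simulates the reactor under the supplied parameter values and returns the
#' concatenated, weighted temperature and substrate residuals
#' (model minus observed) at the observed times. The simulation is evaluated
#' exactly at the observation times through the integrator's dense output.
#'
#' @param values Named list/vector of parameter values (see
#'   [parameter_specs()] for the name vocabulary).
#' @param observed Wide observed table: `time_days` plus any of
#'   `stover_temp_C`, `substrate_g`, `jacket_temp_C`, `condensate_kg`
#'   (`NA` where a channel was not sampled). Jacket and condensate
#'   channels, when present, drive the simulation rather than entering the
#'   residuals.
#' @param config,phases,yields,thermal,controller,air Model objects used as
#'   the base onto which `values` are applied.
#' @param weights Named numeric vector with elements `temperature` and
#'   `substrate`; default is the inverse standard deviation of each
#'   observed channel.
#' @param solver A [solver_options()]; output times are overridden with the
#'   observation times.
#'
#' @return Numeric residual vector, with a `"sim"` attribute carrying the
#'   underlying simulation.
#' @export
residual_vector <- function(values, observed, config, phases,
                            yields = yield_coefficients(),
                            thermal = thermal_params(),
                            controller = jacket_controller(),
                            air = air_properties(),
                            weights = NULL,
                            solver = solver_options()) {
  obs <- split_observed(observed)
  if (is.null(obs$temperature) && is.null(obs$substrate))
    stop("observed table has neither temperature nor substrate data",
         call. = FALSE)
  if (inherits(phases, "growth_phase")) phases <- list(phases)
  mod <- apply_parameter_values(values, config, phases, yields, thermal)

  t_obs <- sort(unique(c(obs$temperature$time_days, obs$substrate$time_days)))
  solver$output_times <- t_obs * 86400
  sim <- simulate_reactor(mod$config, mod$phases, mod$yields, mod$thermal,
                          controller, air, solver,
                          jacket_series = obs$jacket,
                          condensate_series = obs$condensate)
  s <- sim$series

  if (is.null(weights)) {
    sdw <- function(x) {
      v <- stats::sd(x)
      if (is.na(v) || v == 0) 1 else 1 / v
    }
    weights <- c(
      temperature = if (!is.null(obs$temperature)) sdw(obs$temperature$stover_temp_C) else 1,
      substrate = if (!is.null(obs$substrate)) sdw(obs$substrate$substrate_g) else 1)
  }

  res <- numeric(0)
  if (!is.null(obs$temperature)) {
    mt <- stats::approx(s$time_days, s$temperature_C,
                        xout = obs$temperature$time_days, rule = 2)$y
    res <- c(res, weights[["temperature"]] *
               (mt - obs$temperature$stover_temp_C))
  }
  if (!is.null(obs$substrate)) {
    ms <- stats::approx(s$time_days, s$s_deg_total,
                        xout = obs$substrate$time_days, rule = 2)$y
    res <- c(res, weights[["substrate"]] * (ms - obs$substrate$substrate_g))
  }
  attr(res, "sim") <- sim
  res
}

#' Calibrate epistemic model parameters against observed series
#'
#' Bounded nonlinear least squares: the named parameters are mapped through
#' a smooth bijection onto their boxes and fitted with the
#' Levenberg-Marquardt algorithm (parameter tolerance 1e-6) by minimizing
#' the summed squared weighted temperature and substrate residuals.
#'
#' @inheritParams residual_vector
#' @param specs A [parameter_specs()] tibble naming the free parameters,
#'   their starting values and bounds.
#' @param max_iterations Iteration cap for the optimizer.
#' @param prior_sd Width of a weak Tikhonov (ridge) damping term in the
#'   transformed (log / logit) parameter space, appended to the residual
#'   vector as `(z - z_baseline) / prior_sd`. Directions the observations do
#'   not constrain at all (for these reactors, notably the heat yield, whose
#'   effect on the temperature trace is orders of magnitude below the
#'   measurement noise) otherwise drift freely along flat valleys of the
#'   cost surface once the Levenberg-Marquardt damping shrinks. The default
#'   width 10 contributes curvature 0.01 in the transformed space -- far
#'   below the curvature of identified parameters (order 10-100 here) and
#'   far above that of unidentified ones (order 1e-8) -- so estimates of
#'   identified parameters are essentially unaffected while unidentified
#'   ones stay at their baseline. Set to `NULL` for pure least squares.
#' @param multistart Number of additional seeded restarts sampled uniformly
#'   inside the bounds box (0 = single start from the baselines).
#' @param seed Seed for the multistart sampler.
#'
#' @return An object of class `stover_calibration` with elements `fitted`
#'   (named vector), `start`, `specs`, `cost_trajectory`, `residuals`,
#'   `converged`, `message`, `metrics` (mean absolute temperature error and
#'   dry-matter-loss relative error against the observations) and `sim`
#'   (the simulation at the fitted values). Supports [tidy()], [glance()]
#'   and [ggplot2::autoplot()].
#' @export
calibrate_reactor <- function(observed, config, phases, specs,
                              yields = yield_coefficients(),
                              thermal = thermal_params(),
                              controller = jacket_controller(),
                              air = air_properties(),
                              weights = NULL,
                              solver = solver_options(fixed_step = 600),
                              max_iterations = 30, prior_sd = 10,
                              multistart = 0, seed = 1L) {
  stopifnot(is.data.frame(specs),
            all(c("name", "baseline", "lower", "upper") %in% names(specs)))
  obs <- split_observed(observed)
  n_obs <- nrow(obs$temperature %||% data.frame()) +
    nrow(obs$substrate %||% data.frame())
  if (n_obs == 0) stop("no observations to calibrate against", call. = FALSE)
  if (n_obs < nrow(specs))
    stop("fewer residuals (", n_obs, ") than free parameters (",
         nrow(specs), ")", call. = FALSE)
  if (inherits(phases, "growth_phase")) phases <- list(phases)

  # resolve weights once so the cost is comparable across iterations
  if (is.null(weights)) {
    sdw <- function(x) { v <- stats::sd(x); if (is.na(v) || v == 0) 1 else 1 / v }
    weights <- c(
      temperature = if (!is.null(obs$temperature)) sdw(obs$temperature$stover_temp_C) else 1,
      substrate = if (!is.null(obs$substrate)) sdw(obs$substrate$substrate_g) else 1)
  }

  fn_data <- function(z) {
    x <- to_bounded(z, specs$lower, specs$upper)
    names(x) <- specs$name
    r <- residual_vector(as.list(x), observed, config, phases, yields,
                         thermal, controller, air, weights, solver)
    if (!all(is.finite(r)))
      stop("non-finite residuals at parameter values ",
           paste(sprintf("%s = %g", names(x), x), collapse = ", "),
           call. = FALSE)
    as.numeric(r)
  }

  z_prior <- to_unbounded(specs$baseline, specs$lower, specs$upper)
  fn <- if (is.null(prior_sd)) fn_data else
    function(z) c(fn_data(z), (z - z_prior) / prior_sd)

  # Forward-difference Jacobian with a fixed step in the transformed space.
  # The transforms make the coordinates O(1) (log / logit), so a fixed
  # absolute step is a relative step on the natural scale, comfortably
  # above the ODE integration noise that defeats the optimizer's default
  # machine-epsilon-scaled differencing. Ridge rows are appended exactly.
  jac <- function(z, fd_step = 0.01) {
    r0 <- fn_data(z)
    J <- vapply(seq_along(z), function(j) {
      zj <- z
      zj[j] <- zj[j] + fd_step
      (fn_data(zj) - r0) / fd_step
    }, numeric(length(r0)))
    if (is.null(prior_sd)) J else rbind(J, diag(1 / prior_sd, length(z)))
  }

  starts <- list(specs$baseline)
  if (multistart > 0) {
    extra <- withr_seed_draw(seed, multistart, specs)
    starts <- c(starts, extra)
  }

  best <- NULL
  for (x0 in starts) {
    z0 <- to_unbounded(x0, specs$lower, specs$upper)
    # identity scaling: the bound transforms already place every parameter
    # on a comparable O(1) scale, and minpack's column-norm auto-scaling
    # would leave weakly identified directions unpenalized
    fit <- minpack.lm::nls.lm(par = z0, fn = fn, jac = jac,
                              control = minpack.lm::nls.lm.control(
                                ptol = 1e-6, maxiter = max_iterations,
                                diag = as.list(rep(1, length(z0)))))
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }

  fitted <- to_bounded(best$par, specs$lower, specs$upper)
  names(fitted) <- specs$name
  final_res <- residual_vector(as.list(fitted), observed, config, phases,
                               yields, thermal, controller, air, weights,
                               solver)
  sim <- attr(final_res, "sim")

  metrics <- error_report(sim, observed)
  start <- stats::setNames(specs$baseline, specs$name)

  structure(list(
    fitted = fitted, start = start, specs = specs,
    cost_trajectory = as.numeric(best$rsstrace),
    residuals = as.numeric(final_res),
    weights = weights,
    converged = best$info %in% 1:4,
    message = best$message, info = best$info,
    iterations = best$niter,
    metrics = metrics, sim = sim, observed = observed),
    class = "stover_calibration")
}

withr_seed_draw <- function(seed, n, specs) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    lo <- ifelse(is.finite(specs$lower), specs$lower,
                 specs$baseline - abs(specs$baseline))
    hi <- ifelse(is.finite(specs$upper), specs$upper,
                 specs$baseline + abs(specs$baseline))
    stats::runif(nrow(specs), lo, hi)
  })
}

#' Validation error report of a simulation against observations
#'
#' Mean absolute temperature error over the observed temperature series and
#' the dry-matter-loss relative error at quasi-steady state (the final
#' observed substrate point).
#'
#' @param sim A `stover_simulation`.
#' @param observed Wide observed table (see [residual_vector()]).
#'
#' @return A tibble with `mae_temperature`, `relative_error_dml`,
#'   `n_temperature`, `n_substrate`.
#' @export
error_report <- function(sim, observed) {
  stopifnot(inherits(sim, "stover_simulation"))
  obs <- split_observed(observed)
  s <- sim$series
  mae <- NA_real_; n_t <- 0L
  if (!is.null(obs$temperature)) {
    mt <- stats::approx(s$time_days, s$temperature_C,
                        xout = obs$temperature$time_days, rule = 2)$y
    mae <- mean_absolute_error(mt, obs$temperature$stover_temp_C)
    n_t <- nrow(obs$temperature)
  }
  rel <- NA_real_; n_s <- 0L
  if (!is.null(obs$substrate)) {
    n_s <- nrow(obs$substrate)
    last <- obs$substrate[n_s, ]
    dml_obs <- 100 * last$substrate_g / sim$config$loading_dry_matter
    ms <- stats::approx(s$time_days, s$s_deg_total, xout = last$time_days,
                        rule = 2)$y
    dml_mod <- 100 * ms / sim$config$loading_dry_matter
    rel <- relative_error(dml_obs, dml_mod)
  }
  tibble::tibble(mae_temperature = mae, relative_error_dml = rel,
                 n_temperature = n_t, n_substrate = n_s)
}

#' Validate a calibrated parameter set on an independent reactor
#'
#' Runs the forward model for a reactor not used in calibration and reports
#' the temperature and dry-matter-loss errors against its observations.
#'
#' @inheritParams residual_vector
#' @param ... Passed on to [simulate_reactor()].
#'
#' @return A tibble as returned by [error_report()], with the simulation
#'   attached as attribute `"sim"`.
#' @export
validate_reactor <- function(observed, config, phases,
                             yields = yield_coefficients(),
                             thermal = thermal_params(),
                             controller = jacket_controller(),
                             air = air_properties(),
                             solver = solver_options(), ...) {
  obs <- split_observed(observed)
  sim <- simulate_reactor(config, phases, yields, thermal, controller, air,
                          solver, jacket_series = obs$jacket,
                          condensate_series = obs$condensate, ...)
  rep <- error_report(sim, observed)
  attr(rep, "sim") <- sim
  rep
}

#' @export
print.stover_calibration <- function(x, ...) {
  cat("<stover calibration>", length(x$fitted), "parameters,",
      x$iterations, "iterations,",
      if (x$converged) "converged" else "NOT converged", "\n")
  for (nm in names(x$fitted))
    cat(sprintf("  %-14s %.6g  (start %.6g)\n", nm, x$fitted[[nm]],
                x$start[[nm]]))
  cat(sprintf("  cost %.6g -> %.6g; temperature MAE %.3f degC; DML error %.2f%%\n",
              x$cost_trajectory[1], utils::tail(x$cost_trajectory, 1),
              x$metrics$mae_temperature, x$metrics$relative_error_dml))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
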