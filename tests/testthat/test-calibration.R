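test_that("off-gas CO2 converts to substrate by ideal gas and yield", {
  # flat at ambient -> nothing degraded
  tt <- seq(0, 1, by = 1 / 24)
  out <- substrate_from_offgas(tt, rep(410e-6, length(tt)), airflow = 1000,
                               ambient_co2 = 410e-6)
  expect_true(all(out$substrate_g == 0))

  # 1 slpm of 1% net CO2 at 273.15 K for 1 h -> 0.6 L -> ~1.178 g CO2
  tt <- c(0, 1 / 24)
  out <- substrate_from_offgas(tt, rep(0.01 + 410e-6, 2), airflow = 1000,
                               ambient_co2 = 410e-6, temperature_k = 273.15)
  expect_equal(out$co2_g[2], 0.6 / 22.414 * 44.01, tolerance = 1e-3)
  expect_equal(out$co2_g[2], 1.178, tolerance = 1e-3)
  expect_equal(out$substrate_g[2], out$co2_g[2] / 1.44)

  # cumulative CO2 of 1 g corresponds to 1/1.44 g substrate
  expect_equal(out$substrate_g / out$co2_g, c(NaN, 1 / 1.44))

  # sub-ambient samples are clipped with a warning, series non-decreasing
  expect_warning(
    low <- substrate_from_offgas(seq(0, 2, by = 0.5),
                                 c(0.002, 0.0001, 0.003, 0.002, 0.004),
                                 airflow = 500),
    "clipped")
  expect_true(all(diff(low$substrate_g) >= 0))
  expect_error(substrate_from_offgas(c(0, 0), c(0.01, 0.01), 100),
               "strictly increasing")
})

test_that("error metrics implement the defined formulas", {
  expect_equal(mean_absolute_error(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mean_absolute_error(c(2, 1), c(1, 2)), 1.0)
  expect_equal(mean_absolute_error(c(0.3, 0.9, 0.6), c(0, 0, 0)), 0.6)
  expect_equal(mean_absolute_error(c(5, 1), c(1, 5)),
               mean_absolute_error(c(1, 5), c(5, 1)))
  expect_error(mean_absolute_error(1:3, 1:4), "lengths differ")

  expect_equal(relative_error(5.0, 5.1), 2.0, tolerance = 1e-12)
  expect_equal(relative_error(3.7, 3.7), 0)
  expect_equal(relative_error(4.6, 4.7), 100 * 0.1 / 4.6)
  expect_equal(round(relative_error(4.6, 4.7), 1), 2.2)
  expect_error(relative_error(0, 1), "nonzero")

  expect_equal(cost(numeric(0)), 0)
  expect_equal(cost(c(1, 2)), 5)
  expect_equal(cost(c(0.5, -0.5, 2)), 4.5)
  set.seed(31)
  r <- rnorm(20)
  expect_equal(cost(sample(r)), cost(r))
  expect_equal(cost(3 * r), 9 * cost(r))
})

test_that("bound transforms are exact bijections for every bound type", {
  set.seed(32)
  cases <- data.frame(lower = c(0, 35, -Inf, 2, -Inf),
                      upper = c(Inf, 55, Inf, 9, 4))
  for (i in seq_len(nrow(cases))) {
    lo <- cases$lower[i]; up <- cases$upper[i]
    x <- runif(20, max(lo, -50) + 0.1, min(up, 50) - 0.1)
    z <- stoverheat:::to_unbounded(x, lo, up)
    back <- stoverheat:::to_bounded(z, lo, up)
    expect_equal(back, x, tolerance = 1e-9)
    expect_true(all(stoverheat:::to_bounded(rnorm(50, 0, 5), lo, up) >= lo))
    expect_true(all(stoverheat:::to_bounded(rnorm(50, 0, 5), lo, up) <= up))
  }
})

test_that("residual vector is zero for self-generated data and obeys weights", {
  fs <- frozen_scenario(duration_days = 2)
  t_obs <- seq(0, 2 * 86400, by = 3600) / 86400
  solver <- solver_options(fixed_step = 600, output_times = t_obs * 86400)
  sim <- simulate_reactor(fs$config, fs$phase, fs$yields,
                          jacket_series = fs$jacket, solver = solver)
  s <- sim$series
  obs <- tibble::tibble(time_days = s$time_days,
                        stover_temp_C = s$temperature_C,
                        substrate_g = s$s_deg_total,
                        jacket_temp_C = s$jacket_temp_C)
  r0 <- residual_vector(list(), obs, fs$config, fs$phase, yields = fs$yields,
                        solver = solver, weights = c(temperature = 1,
                                                     substrate = 1))
  expect_lt(max(abs(r0)), 1e-9)

  # two temperature points off by +/- 0.5 at unit weight
  obs2 <- obs[c(10, 20), ]
  obs2$substrate_g <- NA
  obs2$stover_temp_C <- obs2$stover_temp_C + c(-0.5, 0.5)
  r <- residual_vector(list(), obs2, fs$config, fs$phase, yields = fs$yields,
                       solver = solver,
                       weights = c(temperature = 1, substrate = 1))
  expect_equal(as.numeric(r), c(0.5, -0.5), tolerance = 1e-8)

  # zero substrate weight removes that block from the cost
  obs3 <- obs
  obs3$substrate_g <- obs3$substrate_g + 5
  r_t <- residual_vector(list(), obs3, fs$config, fs$phase,
                         yields = fs$yields, solver = solver,
                         weights = c(temperature = 1, substrate = 0))
  r_both <- residual_vector(list(), obs3, fs$config, fs$phase,
                            yields = fs$yields, solver = solver,
                            weights = c(temperature = 1, substrate = 1))
  expect_equal(cost(r_t), 0, tolerance = 1e-16)
  expect_gt(cost(r_both), 1)
  expect_error(residual_vector(list(), obs[0, ], fs$config, fs$phase),
               "neither temperature nor substrate")
})

test_that("parameter values map onto the right model components", {
  sc <- biphasic_scenario()
  cfg <- reactor_fixtures()$reactor_2
  mod <- stoverheat:::apply_parameter_values(
    list(t_opt_1 = 44, k_d = 1e-5, y_m = 12, k_cond = 11,
         pool_fraction_1 = 0.6, lag_time_2 = 9, s0_fraction = 0.04),
    cfg, sc$phases, sc$yields, thermal_params())
  expect_equal(mod$phases[[1]]$cardinals$t_opt, 44)
  expect_equal(mod$phases[[2]]$cardinals$t_opt, 38.5)  # untouched
  expect_equal(mod$phases[[1]]$k_d, 1e-5)  # unsuffixed applies to all
  expect_equal(mod$phases[[2]]$k_d, 1e-5)
  expect_equal(mod$phases[[1]]$pool_fraction, 0.6)
  expect_equal(mod$phases[[2]]$pool_fraction, 0.4)
  expect_equal(mod$phases[[2]]$lag_days, 9)
  expect_equal(mod$yields$y_m, 12)
  expect_equal(mod$thermal$k_cond, 11)
  expect_equal(mod$config$s0_fraction, 0.04)
  expect_error(stoverheat:::apply_parameter_values(
    list(bogus = 1), cfg, sc$phases, sc$yields, thermal_params()),
    "unknown calibration parameter")
  expect_error(stoverheat:::apply_parameter_values(
    list(t_opt_3 = 40), cfg, sc$phases, sc$yields, thermal_params()),
    "nonexistent phase")
})

test_that("noiseless calibration recovers the generating parameters", {
  # truth exactly representable on the calibration grid: the identifiable
  # parameters come back at optimizer precision from perturbed starts
  sc <- biphasic_scenario()
  cfg <- reactor_fixtures()$reactor_2
  cfg$duration_days <- 12
  jt <- seq(0, 12 * 86400, by = 3600) / 86400
  jk <- tibble::tibble(time_days = jt,
                       jacket_temp_C = stoverheat:::jacket_program(jt))
  t_obs <- jt
  solver <- solver_options(fixed_step = 600, output_times = t_obs * 86400)
  sim <- simulate_reactor(cfg, sc$phases, sc$yields, jacket_series = jk,
                          solver = solver)
  s <- sim$series
  obs <- tibble::tibble(time_days = s$time_days,
                        stover_temp_C = s$temperature_C,
                        substrate_g = s$s_deg_total,
                        jacket_temp_C = s$jacket_temp_C)
  specs <- parameter_specs(name = c("k_d_1", "t_opt_1"),
                           baseline = c(8.9e-6, 41.3),
                           lower = c(0, 35), upper = c(Inf, 55))
  fit <- calibrate_reactor(obs, cfg, sc$phases, specs, yields = sc$yields,
                           solver = solver, prior_sd = NULL)
  expect_true(fit$converged)
  expect_lt(abs(fit$fitted[["k_d_1"]] - 7.6e-6) / 7.6e-6, 1e-3)
  expect_lt(abs(fit$fitted[["t_opt_1"]] - 46.7) / 46.7, 1e-3)
  # accepted-step cost trajectory is monotone non-increasing
  expect_true(all(diff(fit$cost_trajectory) <= 1e-12))
  # fitted values respect their boxes
  expect_true(all(fit$fitted >= specs$lower & fit$fitted <= specs$upper))
  expect_lte(utils::tail(fit$cost_trajectory, 1), fit$cost_trajectory[1])

  g <- glance(fit)
  expect_true(g$converged)
  expect_lt(g$mae_temperature, 1e-4)
  td <- tidy(fit)
  expect_equal(td$term, c("k_d_1", "t_opt_1"))
  expect_false(any(td$at_bound))
})

test_that("calibration input validation rejects degenerate problems", {
  sc <- biphasic_scenario()
  cfg <- reactor_fixtures()$reactor_2
  specs <- recovery_specs()
  empty <- tibble::tibble(time_days = numeric(0))
  expect_error(calibrate_reactor(empty, cfg, sc$phases, specs),
               "no observations")
  tiny <- tibble::tibble(time_days = c(0, 1), stover_temp_C = c(13, 14))
  expect_error(calibrate_reactor(tiny, cfg, sc$phases, specs),
               "fewer residuals")
  expect_error(parameter_specs("t_opt", 80, 35, 55), "outside bounds")
})

test_that("validation reports temperature MAE and quasi-steady DML error", {
  fs <- frozen_scenario(duration_days = 2)
  solver <- solver_options(output_interval = 3600)
  sim <- simulate_reactor(fs$config, fs$phase, fs$yields,
                          jacket_series = fs$jacket, solver = solver)
  s <- sim$series
  obs <- tibble::tibble(
    time_days = s$time_days,
    stover_temp_C = s$temperature_C + 0.5,          # uniform +0.5 degC shift
    substrate_g = s$s_deg_total * 1.02,             # 2% high at every point
    jacket_temp_C = s$jacket_temp_C)
  rep <- validate_reactor(obs, fs$config, fs$phase, yields = fs$yields,
                          solver = solver)
  expect_equal(rep$mae_temperature, 0.5, tolerance = 1e-6)
  # observed DML is 2% above model: relative error |obs-mod|/obs
  expect_equal(rep$relative_error_dml, 100 * 0.02 / 1.02, tolerance = 1e-3)
  expect_equal(rep$n_temperature, nrow(obs))
})
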