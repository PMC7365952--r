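# Shared scenario builders. Everything is generated in code; no stored data.

# Constant-conditions run with frozen environmental factors: temperature held
# at the optimum (f_T = 1), constant moisture tuned so f_M = f_m, no heat
# sources or sinks. Substrate then follows s0 * (1 - exp(-k_d * f_m * t)).
frozen_scenario <- function(k_d = 8.3e-6, duration_days = 5, t_hold = 30,
                            f_m = 0.5, dm = 7080, s0_fraction = 0.05) {
  m <- 0.2986
  m_half <- m * (1 - f_m) / f_m
  cfg <- reactor_config(t_hold, t_hold, dm, 0,
                        moisture_model(m, m, duration_days, m_half = m_half),
                        duration_days, s0_fraction = s0_fraction)
  list(config = cfg,
       phase = growth_phase(cardinal_temperatures(t_hold - 30, t_hold,
                                                  t_hold + 30), k_d),
       jacket = data.frame(time_days = c(0, duration_days),
                           jacket_temp_C = c(t_hold, t_hold)),
       yields = yield_coefficients(y_co2 = 1.44, y_m = 0),
       f_m = f_m)
}

# Reactor-2 conditions over a shortened horizon with the driven jacket
# program, exercising the bi-phasic lag restart when lag2 < days.
driven_scenario <- function(days = 5, lag2 = 2) {
  sc <- biphasic_scenario()
  cfg <- reactor_fixtures()$reactor_2
  cfg$duration_days <- days
  ph <- sc$phases
  ph[[2]]$lag_days <- lag2
  jt <- seq(0, days * 86400, by = 3600) / 86400
  list(config = cfg, phases = ph, yields = sc$yields,
       jacket = tibble::tibble(
         time_days = jt,
         jacket_temp_C = stoverheat:::jacket_program(jt)))
}

# Thins the generator's 5-minute temperature channel to the hourly grid used
# during calibration (keeps the two channels balanced).
thin_to_hourly <- function(observed) {
  hourly <- (observed$time_days * 24) %% 1 < 1e-9
  observed$stover_temp_C[!hourly] <- NA
  observed[rowSums(!is.na(observed[-1])) > 0, ]
}

recovery_specs <- function() {
  parameter_specs(name = c("k_d_1", "t_opt_1", "y_m", "k_cond"),
                  baseline = c(8.9e-6, 41.3, 10, 9),
                  lower = c(0, 35, 0, 6),
                  upper = c(Inf, 55, Inf, 14))
}

expect_rel_equal <- function(actual, expected, rel_tol, floor = 1e-12) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), floor)), rel_tol)
}
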