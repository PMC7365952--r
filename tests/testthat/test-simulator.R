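test_that("simulation with no heat sources keeps the temperature constant", {
  fs <- frozen_scenario(duration_days = 2)
  sim <- simulate_reactor(fs$config, fs$phase, fs$yields,
                          jacket_series = fs$jacket,
                          solver = solver_options(output_interval = 600))
  expect_lt(max(abs(sim$series$temperature_C - fs$config$t_initial)), 1e-8)
  # substrate still degrades while the thermal state is at rest
  expect_gt(sim$series$s_deg_total[nrow(sim$series)], 0)
})

test_that("single-phase run with frozen factors matches the closed form", {
  fs <- frozen_scenario(k_d = 8.3e-6, duration_days = 5, f_m = 0.5)
  sim <- simulate_reactor(fs$config, fs$phase, fs$yields,
                          jacket_series = fs$jacket,
                          solver = solver_options(rel_tol = 1e-8,
                                                  abs_tol = 1e-10,
                                                  output_interval = 600))
  s <- sim$series
  s0 <- fs$config$s0_fraction * fs$config$loading_dry_matter
  exact <- s0 * (1 - exp(-8.3e-6 * fs$f_m * s$time_s))
  expect_rel_equal(s$s_deg_total[-1], exact[-1], 1e-6)
})

test_that("bi-phasic pools respect the lag and stay monotone", {
  dv <- driven_scenario(days = 5, lag2 = 2)
  sim <- simulate_reactor(dv$config, dv$phases, dv$yields,
                          jacket_series = dv$jacket,
                          solver = solver_options(output_interval = 600))
  s <- sim$series
  expect_true(all(s$s_deg_2[s$time_days <= 2] == 0))
  expect_gt(s$s_deg_2[nrow(s)], 0)
  expect_true(all(diff(s$s_deg_1) >= -1e-9))
  expect_true(all(diff(s$s_deg_2) >= -1e-9))
  expect_true(all(is.finite(s$temperature_C)))
  # per-phase pool bounds
  expect_true(all(s$s_deg_1 <= sim$s0[1] + 1e-6))
  expect_true(all(s$s_deg_2 <= sim$s0[2] + 1e-6))
})

test_that("cumulative CO2 and heat stay exactly proportional to substrate", {
  dv <- driven_scenario(days = 5, lag2 = 2)
  sim <- simulate_reactor(dv$config, dv$phases, dv$yields,
                          jacket_series = dv$jacket,
                          solver = solver_options(output_interval = 600))
  s <- sim$series
  nz <- s$s_deg_total > 0
  expect_lt(max(abs(s$co2_g[nz] / s$s_deg_total[nz] - 1.44)), 1e-12)
  expect_lt(max(abs(s$heat_microbial_J[nz] / s$s_deg_total[nz] - 9.7)), 1e-11)
})

test_that("dry matter loss is the degraded fraction of loading dry matter", {
  # fast kinetics exhaust the pool, so the loss equals s0 / dm exactly
  fs <- frozen_scenario(k_d = 1e-4, duration_days = 5)
  sim <- simulate_reactor(fs$config, fs$phase, fs$yields,
                          jacket_series = fs$jacket,
                          solver = solver_options(output_interval = 3600))
  expect_equal(dry_matter_loss(sim), 100 * 354 / 7080, tolerance = 1e-4)
  expect_equal(dry_matter_loss(sim), 5.0, tolerance = 1e-3)
  expect_equal(dry_matter_loss(sim, loading_dm = 361 / 0.051),
               dry_matter_loss(sim) * 7080 / (361 / 0.051))
  # bounded by the degradable pool
  expect_lte(dry_matter_loss(sim),
             100 * sum(sim$s0) / fs$config$loading_dry_matter + 1e-9)
})

test_that("halving the tolerance leaves the solution within its error bound", {
  dv <- driven_scenario(days = 3)
  s1 <- simulate_reactor(dv$config, dv$phases, dv$yields,
                         jacket_series = dv$jacket,
                         solver = solver_options(rel_tol = 1e-6,
                                                 output_interval = 3600))
  s2 <- simulate_reactor(dv$config, dv$phases, dv$yields,
                         jacket_series = dv$jacket,
                         solver = solver_options(rel_tol = 5e-7,
                                                 output_interval = 3600))
  final1 <- s1$series$s_deg_total[nrow(s1$series)]
  final2 <- s2$series$s_deg_total[nrow(s2$series)]
  expect_lt(abs(final1 - final2) / final2, 1e-6)
})

test_that("observed jacket and condensate series drive the simulation", {
  dv <- driven_scenario(days = 2)
  cond <- tibble::tibble(time_days = 1:2, condensate_kg = c(0.5, 0.25))
  sim <- simulate_reactor(dv$config, dv$phases, dv$yields,
                          jacket_series = dv$jacket,
                          condensate_series = cond,
                          solver = solver_options(output_interval = 3600))
  s <- sim$series
  # piecewise-constant evaporation from the daily volumes
  expect_equal(s$q_evaporation_W[s$time_days < 1],
               rep(-2257e3 * 0.5 / 86400, sum(s$time_days < 1)))
  expect_equal(s$q_evaporation_W[s$time_days > 1 & s$time_days < 2],
               rep(-2257e3 * 0.25 / 86400,
                   sum(s$time_days > 1 & s$time_days < 2)))
  # jacket series is interpolated, not the controller rule
  jfun <- approx(dv$jacket$time_days, dv$jacket$jacket_temp_C,
                 xout = s$time_days)$y
  expect_equal(s$jacket_temp_C, jfun, tolerance = 1e-10)
  bad <- data.frame(time_days = c(0, 2, 1), jacket_temp_C = c(20, 21, 22))
  expect_error(simulate_reactor(dv$config, dv$phases, dv$yields,
                                jacket_series = bad),
               "strictly increasing")
})

test_that("energy is conserved by the integrated run", {
  dv <- driven_scenario(days = 5, lag2 = 2)
  sim <- simulate_reactor(dv$config, dv$phases, dv$yields,
                          jacket_series = dv$jacket,
                          solver = solver_options(output_interval = 60))
  s <- sim$series
  dt <- diff(s$time_s)
  e_q <- sum((s$q_net_W[-1] + s$q_net_W[-nrow(s)]) / 2 * dt)
  e_t <- sum((s$c_th_J_K[-1] + s$c_th_J_K[-nrow(s)]) / 2 *
               diff(s$temperature_C))
  e_abs <- sum((abs(s$q_net_W[-1]) + abs(s$q_net_W[-nrow(s)])) / 2 * dt)
  expect_lt(abs(e_q - e_t) / e_abs, 1e-3)
})

test_that("simulation summaries and tidiers expose the run's quantities", {
  dv <- driven_scenario(days = 2)
  sim <- simulate_reactor(dv$config, dv$phases, dv$yields,
                          jacket_series = dv$jacket,
                          solver = solver_options(output_interval = 3600))
  g <- glance(sim)
  expect_equal(g$dry_matter_loss_pct, dry_matter_loss(sim))
  expect_equal(g$co2_g, 1.44 * g$substrate_degraded_g, tolerance = 1e-12)
  long <- tidy(sim)
  expect_setequal(unique(long$component),
                  c("microbial", "conduction", "convection", "evaporation",
                    "net"))
  p <- ggplot2::autoplot(sim, "temperature")
  expect_s3_class(p, "ggplot")
})
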