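test_that("conductive heat follows the K/L * A * dT law with sign conventions", {
  p <- thermal_params(k_cond = 10.1, area = 0.6, length = 0.08)
  expect_equal(conductive_heat(30.0, 29.5, p), -10.1 / 0.08 * 0.6 * 0.5)
  expect_equal(conductive_heat(30.0, 29.5, p), -37.875)
  expect_equal(conductive_heat(25, 25, p), 0)
  expect_equal(conductive_heat(29.0, 30.0, p), 75.75)
  set.seed(77)
  for (i in 1:20) {
    a <- runif(1, 0, 60); b <- runif(1, 0, 60)
    expect_equal(conductive_heat(a, b, p), -conductive_heat(b, a, p))
  }
})

test_that("jacket controller tracks with offset above threshold, floors below", {
  ctrl <- jacket_controller()
  expect_equal(jacket_temperature(30.0, ctrl), 29.5)
  expect_equal(jacket_temperature(15.0, ctrl), 20.0)
  expect_equal(jacket_temperature(20.4, ctrl), 19.9)
  expect_equal(jacket_temperature(20.0, ctrl), 20.0)  # at threshold: floor
  expect_error(jacket_controller(offset = 0.5), "negative")
})

test_that("convective coefficient follows the turbulent flat-plate correlation", {
  air <- air_properties()
  h <- convective_coefficient(air, 0.1, 0.08)
  # independent evaluation: Re = 510.2, Nu = 0.0296 Re^0.8 Pr^(1/3)
  re <- 0.1 * 0.08 / 1.568e-5
  h_ref <- 0.0296 * re^0.8 * 0.707^(1 / 3) * 0.0263 / 0.08
  expect_equal(h, h_ref, tolerance = 1e-12)
  expect_equal(h, 1.27, tolerance = 0.01)
  expect_equal(convective_coefficient(air, 0, 0.08), 0)
  expect_error(convective_coefficient(air, -0.5), ">= 0")
  # u^0.8 power-law scaling and linearity in k_air
  set.seed(78)
  for (u in runif(5, 0.01, 5)) {
    expect_equal(convective_coefficient(air, 2 * u, 0.08) /
                   convective_coefficient(air, u, 0.08), 2^0.8,
                 tolerance = 1e-10)
  }
  air2 <- air_properties(k_air = 2 * 0.0263)
  expect_equal(convective_coefficient(air2, 1, 0.08),
               2 * convective_coefficient(air, 1, 0.08), tolerance = 1e-10)
})

test_that("convective heat is antisymmetric and scales with h and area", {
  expect_equal(convective_heat(30.0, 24.0, 2.2, 0.6), -7.92)
  expect_equal(convective_heat(24.0, 30.0, 2.2, 0.6), 7.92)
  expect_equal(convective_heat(25, 25, 2.2, 0.6), 0)
  expect_error(convective_heat(25, 30, -1, 0.6), ">= 0")
})

test_that("evaporation heat is a latent-heat loss, never a gain", {
  expect_equal(evaporation_heat(1 / 86400, 2257), -2257e3 / 86400)
  expect_equal(evaporation_heat(1 / 86400, 2257), -26.12, tolerance = 1e-2)
  expect_equal(evaporation_heat(0, 2257), 0)
  expect_equal(evaporation_heat(2 / 86400, 2257),
               2 * evaporation_heat(1 / 86400, 2257))
  set.seed(79)
  expect_true(all(evaporation_heat(runif(50, 0, 1e-3)) <= 0))
  expect_error(evaporation_heat(-1e-6), ">= 0")
})

test_that("default evaporation rate closes the wet-basis water balance", {
  # independent oracle: water mass before/after from wet-basis algebra
  water <- function(dm, m) dm * m / (1 - m)
  mm2 <- moisture_model(0.2986, 0.1693, 34.1)
  rate2 <- default_evaporation_rate(mm2, 7080)
  expect_equal(rate2,
               (water(7080, 0.2986) - water(7080, 0.1693)) / 1000 /
                 (34.1 * 86400), tolerance = 1e-12)
  expect_equal(rate2 * 86400 * 1000, 46, tolerance = 0.5)  # ~46 g/day
  mm3 <- moisture_model(0.2899, 0.1801, 10.7)
  expect_equal(default_evaporation_rate(mm3, 7071),
               (water(7071, 0.2899) - water(7071, 0.1801)) / 1000 /
                 (10.7 * 86400), tolerance = 1e-12)
  expect_equal(default_evaporation_rate(moisture_model(0.25, 0.25, 10), 7080),
               0)
})

test_that("specific heat correlations reproduce the literature ranges", {
  expect_equal(specific_heat_dry(298.15), 0.1031 + 0.00386 * 298.15)
  expect_equal(specific_heat_dry(298.15), 1.254, tolerance = 1e-3)
  expect_equal(specific_heat_dry(373.15), 1.5435, tolerance = 1e-4)
  expect_error(specific_heat_dry(-5), "> 0 K")

  expect_equal(specific_heat_wet(298.15, 0), specific_heat_dry(298.15))
  # independent evaluation of the wet-wood correction
  cw <- function(t, m) (specific_heat_dry(t) + 4.19 * m) / (1 + m) +
    (0.02355 * t - 1.32 * m - 6.191) * m
  expect_equal(specific_heat_wet(298.15, 0.20), cw(298.15, 0.20))
  expect_equal(specific_heat_wet(298.15, 0.30), cw(298.15, 0.30))
  expect_error(specific_heat_wet(298.15, 1.2), "\\[0, 1\\)")

  # consistency ranges: dry wood 1.2-1.5, 20%-moisture wood 1.7-2.3 kJ/kg/K
  expect_gt(specific_heat_dry(298.15), 1.200)
  expect_lt(specific_heat_dry(298.15), 1.500)
  expect_gt(specific_heat_wet(298.15, 0.20), 1.700)
  expect_lt(specific_heat_wet(298.15, 0.20), 2.300)
})

test_that("thermal capacitance composes biomass and stainless terms", {
  p <- thermal_params(v_ss = 0.01)
  expect_equal(7750 * 480 * 0.01, 37200)
  bio <- biomass_properties(7080)
  # loaded-mass basis: wet mass 7.080/(1-0.2986) kg times c_wet, plus steel
  wet_kg <- 7.080 / (1 - 0.2986)
  expect_equal(thermal_capacitance(bio, p, 298.15, 0.2986),
               wet_kg * specific_heat_wet(298.15, 0.2986) * 1000 + 37200)
  # monotone in v_ss and in loaded mass
  p2 <- thermal_params(v_ss = 0.02)
  expect_gt(thermal_capacitance(bio, p2, 298.15, 0.2986),
            thermal_capacitance(bio, p, 298.15, 0.2986))
  bio2 <- biomass_properties(9000)
  expect_gt(thermal_capacitance(bio2, p, 298.15, 0.2986),
            thermal_capacitance(bio, p, 298.15, 0.2986))
  # literal density-times-volume basis
  biodv <- biomass_properties(7080, "density_volume", bulk_density = 942,
                              volume = 0.074)
  expect_equal(thermal_capacitance(biodv, p, 298.15, 0.2),
               942 * 0.074 * specific_heat_wet(298.15, 0.2) * 1000 + 37200)
})

test_that("heat balance sums terms and the node derivative divides by c_th", {
  expect_equal(heat_balance(0, 0, 0, 0), 0)
  expect_equal(heat_balance(10, -5, -2, -1), 2)
  expect_equal(temperature_derivative(74.4, 37200), 0.002)
  expect_equal(temperature_derivative(0, 1000), 0)
  expect_error(temperature_derivative(5, 0), "> 0")
})
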