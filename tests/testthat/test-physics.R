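test_that("saturation vapour pressure matches reference values and is monotone", {
  expect_equal(saturation_vapour_pressure(273.15), 611, tolerance = 1 / 611)
  expect_equal(saturation_vapour_pressure(293.15), 2339, tolerance = 5 / 2339)
  t_grid <- seq(235, 335, by = 0.5)
  expect_true(all(diff(saturation_vapour_pressure(t_grid)) > 0))
  expect_true(all(saturation_vapour_pressure(t_grid) > 0))
  expect_error(saturation_vapour_pressure(200), "out of range")
  expect_error(saturation_vapour_pressure(400), "out of range")
})

test_that("air vapour pressure follows RH and saturates correctly", {
  expect_equal(air_vapour_pressure(std_air(rh = 0)), 0)
  expect_equal(air_vapour_pressure(std_air(rh = 1)),
               saturation_vapour_pressure(293.15))
  expect_equal(air_vapour_pressure(std_air(rh = 0.5)), 1169,
               tolerance = 3 / 1169)
})

test_that("air density matches the ideal-gas law and humidity lowers it", {
  expect_equal(air_density(std_air(rh = 0)), 1.204, tolerance = 0.005)
  # halving pressure halves dry-air density
  expect_equal(air_density(air_state(293.15, 0, 101325)) /
                 air_density(air_state(293.15, 0, 101325 / 2)),
               2, tolerance = 1e-12)
  expect_lt(air_density(std_air(rh = 1)), air_density(std_air(rh = 0)))
  # decreasing in temperature at fixed P, RH
  expect_gt(air_density(air_state(283.15, 0.5)),
            air_density(air_state(303.15, 0.5)))
})

test_that("humid-air specific heat sits at the dry value and rises with RH", {
  expect_equal(humid_air_specific_heat(std_air(rh = 0)), 1005,
               tolerance = 0.01)
  expect_gt(humid_air_specific_heat(std_air(rh = 1)),
            humid_air_specific_heat(std_air(rh = 0)))
  # mixture rule against independently computed specific humidity
  ea <- 0.5 * saturation_vapour_pressure(293.15)
  q <- 0.622 * ea / (101325 - 0.378 * ea)
  expect_equal(humid_air_specific_heat(std_air(rh = 0.5)),
               1005 * (1 - q) + 1860 * q, tolerance = 1e-10)
})

test_that("latent heat matches steam-table values and decreases with T", {
  expect_equal(latent_heat(273.15), 2.501e6, tolerance = 0.002)
  expect_equal(latent_heat(293.15), 2.454e6, tolerance = 0.002)
  expect_gt(latent_heat(283.15), latent_heat(303.15))
})

test_that("photon-to-energy conversion is an exact product", {
  expect_equal(ppfd_to_shortwave(0), 0)
  expect_equal(ppfd_to_shortwave(430, 0.22), 94.6)
  expect_equal(ppfd_to_shortwave(c(100, 200), 0.3), c(30, 60))
  expect_error(ppfd_to_shortwave(-1), "negative")
})

test_that("molar density is P/(RT) and round-trips exactly", {
  expect_equal(molar_density(293.15, 101325), 41.57, tolerance = 1e-3)
  expect_equal(molar_density(293.15, 2 * 101325) /
                 molar_density(293.15, 101325), 2)
  expect_equal(molar_density(2 * 293.15, 101325) /
                 molar_density(293.15, 101325), 0.5)
  t_k <- 300; p <- 9e4
  expect_equal(molar_density(t_k, p) *
                 eb_constants$gas_constant * t_k / p, 1)
})

test_that("heat-to-vapour conductance conversion reproduces leaf-scale g_bw", {
  expect_equal(gbh_to_gbw(0, 293.15), 0)
  # two-sided wheat-like leaf: g_bh 0.0143 m s-1 -> g_bw ~1.28 mol m-2 s-1
  expect_equal(gbh_to_gbw(0.0143, 293.15, 101325, sides = 2), 1.284,
               tolerance = 0.005)
  expect_equal(gbh_to_gbw(0.01, 293.15, sides = 2) /
                 gbh_to_gbw(0.01, 293.15, sides = 1), 2)
})

test_that("property functions are finite and positive across the domain box", {
  set.seed(42)
  for (i in 1:200) {
    air <- air_state(runif(1, 235, 335), runif(1), runif(1, 5.5e4, 1.1e5))
    vals <- c(saturation_vapour_pressure(air$t_air),
              air_vapour_pressure(air), air_density(air),
              humid_air_specific_heat(air), latent_heat(air$t_air),
              molar_density(air$t_air, air$p_atm))
    expect_true(all(is.finite(vals)))
    expect_true(all(vals >= 0))
    expect_gte(humid_air_specific_heat(air), 1003)
  }
})

test_that("air state validates its physical ranges", {
  expect_error(air_state(500), "t_air")
  expect_error(air_state(293, rh = 1.2), "rh")
  expect_error(air_state(293, 0.5, 1e4), "p_atm")
})
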