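test_that("default protocol produces the canonical light steps", {
  env <- make_environment(eb_protocol())
  expect_setequal(unique(env$ppfd), c(0, 430))
  sched <- env_light_schedule(env)
  expect_equal(sched$switch_times[2:3], c(600, 4200), tolerance = 1e-9)
  expect_equal(sched$levels, c(0, 430, 0))
})

test_that("environmental drifts hit their specified endpoints exactly", {
  proto <- eb_protocol(durations = c(100, 200, 100), sampling_s = 5,
                       t_air_drift = c(0, 1.5, -0.5),
                       rh_drift = c(0, -0.04, 0.02))
  env <- make_environment(proto)
  at <- function(t) env[env$time == t, ]
  expect_equal(at(100)$t_air, 293.15)
  expect_equal(at(300)$t_air, 293.15 + 1.5)
  expect_equal(at(400)$t_air, 293.15 + 1.0)
  expect_equal(at(300)$rh, 0.5 - 0.04)
  # zero drift means exactly constant channels
  env0 <- make_environment(eb_protocol(durations = c(100, 100, 100),
                                       t_air_drift = 0, rh_drift = 0))
  expect_equal(var(env0$t_air), 0)
  expect_equal(var(env0$rh), 0)
})

test_that("simulated traces obey physical orderings", {
  pr <- fixture_props()
  proto <- quick_protocol(noise_sd = 0, seed = 30)
  sim <- simulate_experiment(proto, pr$leaf, stomatal_kinetics(),
                             pr$black, pr$white)
  light <- sim$env$time > 400 & sim$env$time < 1150
  # black absorbs more than white: warmer in the light
  expect_true(all(sim$black$value[light] > sim$white$value[light]))
  # steady-state oracle gives the same ordering at the light plateau
  air <- air_state(sim$env$t_air[200], sim$env$rh[200])
  is_ref <- ppfd_to_shortwave(430) * proto$ref_light_fraction
  ssb <- steady_state_temperature(sim$truth$ref_props_black, air, is_ref)
  ssw <- steady_state_temperature(sim$truth$ref_props_white, air, is_ref)
  expect_gt(ssb, ssw)
})

test_that("identical reference properties give identical traces up to noise", {
  pr <- fixture_props()
  proto <- quick_protocol(noise_sd = 0, seed = 31)
  sim <- simulate_experiment(proto, pr$replica, 0.2, pr$black, pr$black)
  expect_equal(sim$black$value, sim$white$value, tolerance = 1e-7)
})

test_that("noise realisation is reproducible from the seed", {
  pr <- fixture_props()
  proto <- quick_protocol(seed = 99)
  a <- simulate_experiment(proto, pr$replica, 0.2, pr$black, pr$white)
  b <- simulate_experiment(proto, pr$replica, 0.2, pr$black, pr$white)
  expect_identical(a$leaf$value, b$leaf$value)
  c2 <- simulate_experiment(proto, pr$replica, 0.2, pr$black, pr$white,
                            seed = 100)
  expect_false(identical(a$leaf$value, c2$leaf$value))
})

test_that("wet replica runs cooler than dry, and zero pore density closes the gap", {
  pr <- fixture_props()
  proto <- quick_protocol(noise_sd = 0, seed = 32)
  rep_sim <- simulate_replica(proto, paper_geometry(), pr$replica)
  light <- rep_sim$env$time > 400 & rep_sim$env$time < 1180
  expect_true(all(rep_sim$wet$value[light] < rep_sim$dry$value[light]))
  expect_equal(rep_sim$g_pore, 0.207, tolerance = 0.02)
  none <- simulate_replica(proto,
                           pore_geometry(0.5e-3, 40e-6, 0), pr$replica)
  expect_equal(none$wet$value, none$dry$value, tolerance = 1e-7)
})

test_that("the steady wet-dry gap agrees with the linearized budget estimate", {
  pr <- fixture_props()
  proto <- eb_protocol(durations = c(300, 3000, 300), sampling_s = 10,
                       noise_sd = 0, t_air_drift = 0, rh_drift = 0,
                       seed = 33)
  rep_sim <- simulate_replica(proto, paper_geometry(), pr$replica)
  late <- rep_sim$env$time > 2800 & rep_sim$env$time < 3300
  gap <- mean(rep_sim$dry$value[late] - rep_sim$wet$value[late])
  air <- air_state(293.15, 0.5)
  t_wet <- mean(rep_sim$wet$value[late])
  g_bw <- gbh_to_gbw(pr$replica$g_bh, 293.15, sides = 1)
  g_tw <- total_conductance(g_bw, rep_sim$g_pore)
  le <- latent_heat(t_wet) * transpiration(g_tw, t_wet, air)
  th <- eb_constants$stefan_boltzmann
  denom <- 8 * th * pr$replica$epsilon * t_wet^3 +
    2 * pr$replica$g_bh * air_density(air) * humid_air_specific_heat(air)
  expect_equal(gap, le / denom, tolerance = 0.2)
})

test_that("ground truth record carries everything needed for recovery scoring", {
  pr <- fixture_props()
  sim <- simulate_experiment(quick_protocol(seed = 34), pr$leaf,
                             stomatal_kinetics(), pr$black, pr$white)
  expect_named(sim, c("leaf", "black", "white", "env", "truth"))
  expect_s3_class(sim$truth$gs_params, "stomatal_kinetics")
  expect_equal(sim$truth$ref_props_black$light_fraction, 300 / 430)
  expect_equal(length(sim$truth$leaf_clean$value), nrow(sim$env))
})
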