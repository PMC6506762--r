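leaf <- thermal_object(alpha = 0.7, epsilon = 0.96, k = 900,
                       g_bh = 0.0143, transpiring_sides = 2)

test_that("net radiation assembles its three terms correctly", {
  th <- eb_constants$stefan_boltzmann
  zero <- thermal_object(alpha = 0, epsilon = 0, k = 1)
  expect_equal(net_radiation(zero, 500, 300), 0)
  # constructed radiative equilibrium
  obj <- thermal_object(alpha = 0.96, epsilon = 0.96, k = 1)
  expect_equal(net_radiation(obj, 0, 293.15,
                             L_d = 2 * th * 0.96 * 293.15^4), 0)
  # hand computation of all three terms
  expect_equal(net_radiation(obj, 100, 293.15,
                             L_d = 2 * th * 0.96 * 288.15^4),
               0.96 * 100 - 2 * th * 0.96 * 293.15^4 +
                 2 * th * 0.96 * 288.15^4)
})

test_that("sensible heat is symmetric in the temperature difference", {
  air <- std_air(rh = 0)
  obj <- thermal_object(0.5, 0.9, 900, g_bh = 0.01)
  expect_equal(sensible_heat(obj, air$t_air, air), 0)
  expect_equal(sensible_heat(obj, air$t_air + 1, air), 24.2,
               tolerance = 0.005)
  expect_equal(sensible_heat(obj, air$t_air + 2, air),
               -sensible_heat(obj, air$t_air - 2, air))
})

test_that("series conductance handles limits and matches the harmonic value", {
  expect_equal(total_conductance(1e12, 0.5), 0.5, tolerance = 1e-9)
  expect_equal(total_conductance(0.4, 0.4), 0.2)
  expect_equal(total_conductance(1.284, 0.5), 0.3599, tolerance = 1e-4)
  expect_equal(total_conductance(0, 0.5), 0)
  expect_equal(total_conductance(0.5, 0), 0)
})

test_that("transpiration matches a term-by-term hand computation", {
  air <- std_air()
  expect_equal(transpiration(0, 294.15, air), 0)
  # saturated air at leaf temperature -> zero gradient
  sat <- air_state(294.15, saturation_vapour_pressure(294.15) /
                     saturation_vapour_pressure(294.15))
  expect_equal(transpiration(0.36, 294.15, sat), 0, tolerance = 1e-15)
  manual <- 0.622 * air_density(air) / 101325 *
    (eb_constants$gas_constant * 294.15 / 101325) * 0.36 *
    (saturation_vapour_pressure(294.15) - air_vapour_pressure(air))
  expect_equal(transpiration(0.36, 294.15, air), manual)
  expect_warning(
    transpiration(0.3, 285, air_state(293.15, 0.9)), "clamped")
})

test_that("flux breakdown satisfies the storage identity exactly", {
  air <- std_air()
  fb <- flux_breakdown(leaf, 94.6, 292.5, air, L_d = 800, latent = 60)
  expect_identical(fb$storage, fb$Rn - fb$C - fb$latent)
})

test_that("differenced derivative collapses to the reference's when objects are identical", {
  proto <- quick_protocol(seed = 1)
  env <- make_environment(proto)
  es <- env_signals(env, exact = TRUE)
  ref <- smooth_signal(eb_trace(env$time, 294 + 0.5 * sin(env$time / 300)))
  same <- thermal_object(0.9, 0.95, 1500, 0.012)
  for (t in c(50, 700, 1900)) {
    expect_equal(differenced_rhs(ref$value(t), t, ref, es, same, same, 0),
                 ref$deriv(t), tolerance = 1e-10)
    # a latent flux can only cool relative to the reference
    expect_lt(differenced_rhs(ref$value(t), t, ref, es, same, same, 50),
              ref$deriv(t))
  }
})

test_that("differenced form equals the difference of full budgets plus the reference storage", {
  # algebraic identity: for shared L_d, dT1 = (k2 dT2 + [budget1 - budget2
  # with L_d cancelled]) / k1, where budget differences are computed from
  # net_radiation and sensible_heat directly
  proto <- quick_protocol(seed = 2)
  es <- env_signals(make_environment(proto), exact = TRUE)
  ref <- smooth_signal(eb_trace(seq(0, 2100, 5),
                                295 + 0.3 * cos(seq(0, 2100, 5) / 400)))
  p1 <- thermal_object(0.7, 0.96, 900, 0.0143, transpiring_sides = 2)
  p2 <- thermal_object(0.96, 0.96, 2300, 0.0143)
  set.seed(4)
  for (i in 1:20) {
    t <- runif(1, 10, 2000)
    t1 <- runif(1, 288, 300)
    ld <- runif(1, 600, 900)
    lat <- runif(1, 0, 80)
    air <- env_air_at(es, t)
    b1 <- net_radiation(p1, env_is_at(es, t, 1), t1, ld) -
      sensible_heat(p1, t1, air) - lat
    t2 <- ref$value(t)
    b2 <- net_radiation(p2, env_is_at(es, t, 1), t2, ld) -
      sensible_heat(p2, t2, air)
    oracle <- (p2$k * ref$deriv(t) + b1 - b2) / p1$k
    expect_equal(differenced_rhs(t1, t, ref, es, p1, p2, lat), oracle,
                 tolerance = 1e-10)
  }
})

test_that("identity case: zero conductance and equal objects reproduce the reference", {
  proto <- quick_protocol(noise_sd = 0, seed = 5)
  pr <- fixture_props()
  sim <- simulate_experiment(proto, pr$black, 0, pr$black, pr$white)
  es <- env_signals(sim$env, exact = TRUE)
  # noiseless input: full-resolution segmented interpolation
  ref <- smooth_signal(sim$black, breaks = es$switch_times,
                       nknots = 1e6, exp_trend = FALSE)
  same <- sim$truth$ref_props_black
  pred <- predict_temperature(same, same, ref, es, conductance = 0,
                              times = sim$black$time)
  # residual error is the interpolated derivative right at the light
  # switch (finite sampling), not the solver: sub-millikelvin
  expect_lt(max(abs(pred$value - sim$black$value)), 1e-3)
})

test_that("terminal temperature under constant environment matches the steady-state root", {
  env <- environment_trace(seq(0, 4000, 10), ppfd = 430,
                           t_air = 293.15, rh = 0.5)
  es <- env_signals(env, exact = TRUE)
  air <- air_state(293.15, 0.5)
  p2 <- thermal_object(0.96, 0.96, 2300, 0.0143)
  p1 <- thermal_object(0.7, 0.96, 900, 0.0143, transpiring_sides = 2)
  ld <- 2 * eb_constants$stefan_boltzmann * 293.15^4
  t2_ss <- steady_state_temperature(p2, air, ppfd_to_shortwave(430))
  ref <- smooth_signal(eb_trace(env$time, rep(t2_ss, length(env$time))))
  for (gs in c(0.4)) {
    pred <- predict_temperature(p1, p2, ref, es, conductance = gs,
                                t1_0 = 290, times = env$time)
    ss <- steady_state_temperature(p1, air, ppfd_to_shortwave(430),
                                   L_d = ld, gs = gs)
    expect_lt(abs(pred$value[length(pred$value)] - ss), 1e-3)
  }
})

test_that("stiff solver matches a fixed-step RK4 oracle", {
  # a finer-step oracle comparison on the full 10-minute protocol runs
  # with the acceptance checks; this one guards the module quickly
  proto <- eb_protocol(durations = c(60, 150, 90), sampling_s = 3,
                       noise_sd = 0, seed = 6)
  pr <- fixture_props()
  sk <- stomatal_kinetics(tau_i = 100, tau_d = 150, phi_i = 30, phi_d = 30)
  sim <- simulate_experiment(proto, pr$leaf, sk, pr$black, pr$white)
  es <- env_signals(sim$env, exact = TRUE)
  ref <- smooth_signal(sim$black)
  sched <- protocol_schedule(proto)
  t1_0 <- sim$truth$leaf_clean$value[1]
  pred <- predict_temperature(pr$leaf, sim$truth$ref_props_black, ref, es,
                              conductance = sk, schedule = sched,
                              t1_0 = t1_0, times = sim$black$time,
                              control = solver_control(rtol = 1e-8,
                                                       atol = 1e-10))
  span <- sum(c(60, 150, 90))
  gs_fun <- function(t) pmax(gs_schedule(min(max(t, 0), span), sk, sched),
                             1e-6)
  rhs <- function(y, t) {
    t <- min(max(t, 0), span)
    lat <- leafeb:::latent_flux(y, t, gs_fun(t), es, pr$leaf)
    differenced_rhs(y, t, ref, es, pr$leaf,
                    sim$truth$ref_props_black, lat)
  }
  oracle <- rk4(rhs, t1_0, sim$black$time, dt = 0.05)
  expect_lt(max(abs(pred$value - oracle)), 1e-3)
})

test_that("compiled and R solver engines agree", {
  proto <- quick_protocol(seed = 7)
  pr <- fixture_props()
  sk <- stomatal_kinetics()
  sim <- simulate_experiment(proto, pr$leaf, sk, pr$black, pr$white)
  es <- env_signals(sim$env)
  ref <- smooth_signal(sim$black, breaks = es$switch_times)
  sched <- protocol_schedule(proto)
  args <- list(pr$leaf, sim$truth$ref_props_black, ref, es,
               conductance = sk, schedule = sched,
               t1_0 = sim$truth$leaf_clean$value[1],
               times = sim$black$time,
               control = solver_control(rtol = 1e-8, atol = 1e-10,
                                        forcing_dt = 1))
  pc <- do.call(predict_temperature, c(args, engine = "compiled"))
  pr_ <- do.call(predict_temperature, c(args, engine = "R"))
  expect_lt(max(abs(pc$value - pr_$value)), 2e-3)
})

test_that("halving solver tolerances moves the trajectory less than the tolerance", {
  proto <- quick_protocol(noise_sd = 0, seed = 8)
  pr <- fixture_props()
  sim <- simulate_experiment(proto, pr$replica, 0.2, pr$black, pr$white)
  es <- env_signals(sim$env, exact = TRUE)
  ref <- smooth_signal(sim$black, breaks = es$switch_times)
  base <- predict_temperature(pr$replica, sim$truth$ref_props_black, ref,
                              es, conductance = 0.2,
                              times = sim$black$time,
                              control = solver_control(rtol = 1e-6,
                                                       atol = 1e-8))
  tight <- predict_temperature(pr$replica, sim$truth$ref_props_black, ref,
                               es, conductance = 0.2,
                               times = sim$black$time,
                               control = solver_control(rtol = 5e-7,
                                                        atol = 5e-9))
  # the looser run's error budget is rtol * |T| ~ 3e-4 K
  expect_lt(max(abs(base$value - tight$value)), 1e-3)
})

test_that("step response initial slope and linearized relaxation match theory", {
  # step in shortwave from equilibrium: initial slope alpha * dI / k
  air <- air_state(293.15, 0.5)
  env <- environment_trace(seq(0, 2000, 5),
                           ppfd = rep(c(0, 430), c(2, 399)),
                           t_air = 293.15, rh = 0.5)
  es <- env_signals(env, exact = TRUE)
  obj <- thermal_object(0.9, 0.95, 1200, 0.012)
  ld <- 2 * eb_constants$stefan_boltzmann * 293.15^4
  t_eq <- steady_state_temperature(obj, air, 0, L_d = ld)
  slope <- full_budget_rhs(t_eq, 10, obj, es, L_d = ld)
  expect_equal(slope, 0.9 * ppfd_to_shortwave(430) / 1200,
               tolerance = 1e-6)
  # linearized time constant k / (8 theta eps T^3 + 2 g_bh rho Cs)
  th <- eb_constants$stefan_boltzmann
  tau_lin <- 1200 / (8 * th * 0.95 * t_eq^3 +
                       2 * 0.012 * air_density(air) *
                         humid_air_specific_heat(air))
  t_new <- steady_state_temperature(obj, air, ppfd_to_shortwave(430),
                                    L_d = ld)
  rhs <- function(y, t) full_budget_rhs(y, max(t, 10), obj, es, L_d = ld)
  traj <- rk4(rhs, t_eq, seq(10, 10 + 3 * tau_lin, 5), dt = 0.05)
  # after one linearized time constant the gap closed to ~ 1/e
  gap <- (t_new - traj) / (t_new - t_eq)
  idx <- which.min(abs(seq(10, 10 + 3 * tau_lin, 5) - (10 + tau_lin)))
  expect_equal(gap[idx], exp(-1), tolerance = 0.05)
})
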