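#' Experimental protocol for the forward simulator
#'
#' Describes a dark/light/dark step experiment in a phenotyping cabinet:
#' phase durations and light levels, the (slightly lower) irradiance at
#' the reference site, slow piecewise-linear drifts of air temperature and
#' humidity, the wall temperature that sets the incident longwave, camera
#' noise and the frame cadence.
#'
#' Defaults reproduce the protocol the package is designed around: 10 min
#' dark, 1 h at 430 umol m-2 s-1, 1 h dark, references receiving
#' 300 umol m-2 s-1 during the light phase, frames every 3 s, and camera
#' noise of 0.03 K (a microbolometer NETD figure).
#'
#' @param durations phase durations, s.
#' @param levels PPFD per phase at the target site, umol m-2 s-1.
#' @param ref_light_fraction fraction of the nominal PPFD received at the
#'   reference site.
#' @param t_air0 initial air temperature, K.
#' @param rh0 initial relative humidity, fraction.
#' @param p_atm atmospheric pressure, Pa (constant).
#' @param t_air_drift per-phase linear change in air temperature, K.
#' @param rh_drift per-phase linear change in relative humidity, fraction.
#' @param t_wall wall temperature for the longwave environment, K; `NULL`
#'   (default) makes the walls track the air temperature.
#' @param noise_sd camera noise standard deviation, K.
#' @param sampling_s frame interval, s.
#' @param ppfd_factor radiation conversion factor, J umol-1.
#' @param seed integer seed for the noise realisation.
#' @return An object of class `eb_protocol`.
#' @export
eb_protocol <- function(durations = c(600, 3600, 3600),
                        levels = c(0, 430, 0),
                        ref_light_fraction = 300 / 430,
                        t_air0 = 293.15, rh0 = 0.5, p_atm = 101325,
                        t_air_drift = c(0, 1.0, -0.5),
                        rh_drift = c(0, -0.03, 0.02),
                        t_wall = NULL, noise_sd = 0.03, sampling_s = 3,
                        ppfd_factor = 0.22, seed = NULL) {
  np <- length(durations)
  stopifnot(all(durations > 0), length(levels) == np, noise_sd >= 0,
            sampling_s > 0)
  t_air_drift <- rep_len(t_air_drift, np)
  rh_drift <- rep_len(rh_drift, np)
  structure(list(durations = durations, levels = levels,
                 ref_light_fraction = ref_light_fraction,
                 t_air0 = t_air0, rh0 = rh0, p_atm = p_atm,
                 t_air_drift = t_air_drift, rh_drift = rh_drift,
                 t_wall = t_wall, noise_sd = noise_sd,
                 sampling_s = sampling_s, ppfd_factor = ppfd_factor,
                 seed = seed),
            class = "eb_protocol")
}

#' Build the environmental trace of a protocol
#'
#' PPFD is an exact step function at the phase switch times; air
#' temperature and humidity follow their piecewise-linear drift
#' specification; pressure is constant.
#'
#' @param protocol an [eb_protocol()].
#' @return An [environment_trace()].
#' @export
make_environment <- function(protocol) {
  stopifnot(inherits(protocol, "eb_protocol"))
  bounds <- c(0, cumsum(protocol$durations))
  total <- bounds[length(bounds)]
  tt <- seq(0, total, by = protocol$sampling_s)
  if (tt[length(tt)] < total) tt <- c(tt, total)
  phase <- pmin(findInterval(tt, bounds, rightmost.closed = TRUE),
                length(protocol$levels))
  ppfd <- protocol$levels[phase]
  drift_curve <- function(x0, deltas) {
    nodes <- x0 + c(0, cumsum(deltas))
    stats::approx(bounds, nodes, xout = tt)$y
  }
  environment_trace(tt, ppfd,
                    t_air = drift_curve(protocol$t_air0,
                                        protocol$t_air_drift),
                    rh = drift_curve(protocol$rh0, protocol$rh_drift),
                    p_atm = protocol$p_atm,
                    ppfd_factor = protocol$ppfd_factor)
}

#' @rdname make_environment
#' @export
protocol_schedule <- function(protocol) {
  light_schedule(c(0, cumsum(protocol$durations)), protocol$levels)
}

# longwave received from the walls (both sides aggregated), W m-2
wall_longwave <- function(protocol, env_sig) {
  th <- eb_constants$stefan_boltzmann
  if (is.null(protocol$t_wall)) {
    function(t) 2 * th * env_sig$t_air$value(t)^4
  } else {
    tw <- protocol$t_wall
    function(t) 2 * th * tw^4
  }
}

#' Fixture object properties for simulation and examples
#'
#' A consistent set of plausible object properties: a wheat-like leaf
#' (absorbance 0.7, emissivity 0.96, areal heat capacity 900 J m-2 K-1,
#' amphistomatous), black and white aluminium references cut from the same
#' 0.95 mm sheet (shared k of about 2309 J m-2 K-1), and a replica plate
#' (black tape side: absorbance 0.96, emissivity 0.97) transpiring from
#' one face.  These are simulation fixtures, not measured values.
#'
#' @param g_bh boundary-layer conductance to heat shared by all objects,
#'   m s-1.
#' @return A named list of [thermal_object()]s: `leaf`, `black`, `white`,
#'   `replica`.
#' @export
fixture_props <- function(g_bh = 0.0143) {
  k_ref <- 0.95e-3 * 2700 * 900    # aluminium sheet: thickness*rho*cp
  list(
    leaf = thermal_object(alpha = 0.7, epsilon = 0.96, k = 900,
                          g_bh = g_bh, transpiring_sides = 2),
    black = thermal_object(alpha = 0.96, epsilon = 0.96, k = k_ref,
                           g_bh = g_bh),
    white = thermal_object(alpha = 0.25, epsilon = 0.92, k = k_ref,
                           g_bh = g_bh),
    replica = thermal_object(alpha = 0.96, epsilon = 0.97, k = 2300,
                             g_bh = g_bh, transpiring_sides = 1)
  )
}

# integrate the full single-object budget phase by phase (the light steps
# are genuine discontinuities of the driver)
integrate_budget <- function(props, env_sig, ld_fun, gs_fun, t0_val,
                             times, switch_times,
                             rtol = 1e-8, atol = 1e-8) {
  dom <- env_sig$domain
  rhs <- function(t, y, parms) {
    t <- min(max(t, dom[1]), dom[2])  # lsoda may probe past the ends
    gs <- gs_fun(t)
    lat <- latent_flux(y[1], t, gs, env_sig, props)
    list(full_budget_rhs(y[1], t, props, env_sig, ld_fun(t), lat))
  }
  segs <- sort(unique(c(times[1], switch_times, times[length(times)])))
  segs <- segs[segs >= times[1] & segs <= times[length(times)]]
  y <- t0_val
  out_t <- numeric(0); out_y <- numeric(0)
  for (i in seq_len(length(segs) - 1)) {
    sel <- times >= segs[i] & times <= segs[i + 1]
    tt <- sort(unique(c(segs[i], times[sel], segs[i + 1])))
    sol <- deSolve::ode(y = y, times = tt, func = rhs, parms = NULL,
                        method = "lsoda", rtol = rtol, atol = atol,
                        hmax = 5)
    if (attr(sol, "istate")[1] < 0)
      stop("forward simulation failed at t = ", max(sol[, 1]))
    keep <- sol[, 1] %in% times[sel] & !(sol[, 1] %in% out_t)
    out_t <- c(out_t, sol[keep, 1]); out_y <- c(out_y, sol[keep, 2])
    y <- sol[nrow(sol), 2]
  }
  list(time = out_t, value = out_y)
}

#' Forward-simulate a complete experiment
#'
#' Integrates the full energy budget of the target object (leaf or
#' replica) and of the black and white references under a shared longwave
#' environment, starts every object at its pre-protocol steady state, adds
#' seeded iid Gaussian camera noise, and returns the traces together with
#' the exact ground-truth record needed to score recovery.
#'
#' @param protocol an [eb_protocol()].
#' @param leaf_props target-object properties ([thermal_object()]).
#' @param gs_params a [stomatal_kinetics()] object, or a single fixed
#'   conductance (mol m-2 s-1) for replica-style targets.
#' @param ref_props_black,ref_props_white reference properties; their
#'   `light_fraction` is overridden by the protocol's
#'   `ref_light_fraction`.
#' @param seed overrides `protocol$seed` for the noise realisation.
#' @return A list with `leaf`, `black`, `white` ([eb_trace()]s, K), `env`
#'   (the [environment_trace()]), and `truth` (named list of every
#'   generating parameter, including the noiseless trajectories).
#' @export
simulate_experiment <- function(protocol, leaf_props, gs_params,
                                ref_props_black, ref_props_white,
                                seed = NULL) {
  stopifnot(inherits(protocol, "eb_protocol"))
  env <- make_environment(protocol)
  es <- env_signals(env, exact = TRUE)
  sched <- protocol_schedule(protocol)
  ld <- wall_longwave(protocol, es)
  ref_props_black$light_fraction <- protocol$ref_light_fraction
  ref_props_white$light_fraction <- protocol$ref_light_fraction
  gs_fun <- make_gs_fun(gs_params, sched, gs_clamp = 0)
  air0 <- env_air_at(es, 0)
  sw <- es$switch_times
  run <- function(props, gfun, gs0) {
    t0 <- steady_state_temperature(props, air0,
                                   env_is_at(es, 0, props$light_fraction),
                                   L_d = ld(0), gs = gs0)
    integrate_budget(props, es, ld, gfun, t0, env$time, sw)
  }
  leaf_clean <- run(leaf_props, gs_fun, gs_fun(0))
  black_clean <- run(ref_props_black, function(t) 0, 0)
  white_clean <- run(ref_props_white, function(t) 0, 0)

  seed <- if (!is.null(seed)) seed else protocol$seed
  if (!is.null(seed)) set.seed(seed)
  noisy <- function(cl) {
    eb_trace(cl$time, cl$value + stats::rnorm(length(cl$value), 0,
                                              protocol$noise_sd))
  }
  list(
    leaf = noisy(leaf_clean), black = noisy(black_clean),
    white = noisy(white_clean), env = env,
    truth = list(protocol = protocol, leaf_props = leaf_props,
                 gs_params = gs_params, ref_props_black = ref_props_black,
                 ref_props_white = ref_props_white, seed = seed,
                 leaf_clean = leaf_clean, black_clean = black_clean,
                 white_clean = white_clean)
  )
}

#' Forward-simulate a wet and a dry leaf replica
#'
#' The wet replica transpires from its felt face at the fixed conductance
#' implied by the membrane's pore geometry; the dry replica is the same
#' plate with no latent flux.
#'
#' @param protocol an [eb_protocol()].
#' @param geom a [pore_geometry()].
#' @param plate_props replica plate properties ([thermal_object()]); its
#'   `transpiring_sides` is forced to 1 for the wet and 0 for the dry run.
#' @param seed noise seed (overrides `protocol$seed`).
#' @return A list with `wet`, `dry` ([eb_trace()]s), `g_pore`
#'   (mol m-2 s-1), `env` and the noiseless trajectories in `truth`.
#' @export
simulate_replica <- function(protocol, geom, plate_props, seed = NULL) {
  g_pore <- pore_conductance(geom, protocol$t_air0, protocol$p_atm)
  wet_props <- plate_props; wet_props$transpiring_sides <- 1
  dry_props <- plate_props; dry_props$transpiring_sides <- 0
  env <- make_environment(protocol)
  es <- env_signals(env, exact = TRUE)
  ld <- wall_longwave(protocol, es)
  air0 <- env_air_at(es, 0)
  run <- function(props, gs) {
    t0 <- steady_state_temperature(props, air0,
                                   env_is_at(es, 0, props$light_fraction),
                                   L_d = ld(0), gs = gs)
    integrate_budget(props, es, ld, function(t) gs, t0, env$time,
                     es$switch_times)
  }
  wet_clean <- run(wet_props, g_pore)
  dry_clean <- run(dry_props, 0)
  seed <- if (!is.null(seed)) seed else protocol$seed
  if (!is.null(seed)) set.seed(seed)
  noisy <- function(cl)
    eb_trace(cl$time, cl$value + stats::rnorm(length(cl$value), 0,
                                              protocol$noise_sd))
  list(wet = noisy(wet_clean), dry = noisy(dry_clean), g_pore = g_pore,
       env = env,
       truth = list(wet_clean = wet_clean, dry_clean = dry_clean,
                    geom = geom, plate_props = plate_props, seed = seed))
}
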