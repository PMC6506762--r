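#' Net radiation of a horizontal two-sided object
#'
#' Absorbed shortwave minus longwave emitted by both faces, plus the
#' longwave received from the surroundings.  `L_d` only matters for
#' forward simulation: it cancels identically in the reference-differenced
#' model, which is the point of differencing.
#'
#' @param props a [thermal_object()].
#' @param I_s incident shortwave at the object's site, W m-2.
#' @param t_k object temperature, K.
#' @param L_d longwave received from the surroundings (both sides
#'   aggregated), W m-2.
#' @return Net radiation, W m-2.
#' @export
net_radiation <- function(props, I_s, t_k, L_d = 0) {
  stopifnot(all(t_k > 0))
  props$alpha * I_s -
    2 * eb_constants$stefan_boltzmann * props$epsilon * t_k^4 + L_d
}

#' Sensible heat exchanged with the air
#'
#' Conductive/convective loss from both faces:
#' `C = 2 g_bh rho C_s (T - T_air)`.
#'
#' @param props a [thermal_object()].
#' @param t_k object temperature, K.
#' @param air an [air_state()].
#' @return Sensible heat flux, W m-2 (positive when the object is warmer
#'   than the air).
#' @export
sensible_heat <- function(props, t_k, air) {
  stopifnot(all(t_k > 0))
  2 * props$g_bh * air_density(air) * humid_air_specific_heat(air) *
    (t_k - air$t_air)
}

#' Series combination of boundary-layer and stomatal conductance
#'
#' @param g_bw boundary-layer conductance to water vapour, mol m-2 s-1.
#' @param g_sw stomatal (or pore) conductance, mol m-2 s-1.
#' @return Total conductance `1 / (1/g_bw + 1/g_sw)`, mol m-2 s-1; zero if
#'   either branch is zero.
#' @export
total_conductance <- function(g_bw, g_sw) {
  stopifnot(all(g_bw >= 0), all(g_sw >= 0))
  ifelse(g_bw <= 0 | g_sw <= 0, 0, 1 / (1 / g_bw + 1 / g_sw))
}

#' Transpiration rate
#'
#' Mass flux of water vapour through the total conductance chain, driven
#' by the leaf-to-air vapour pressure gradient:
#' `E = (0.622 rho / P) (R T_leaf / P) g_tw (e_s(T_leaf) - e_a)`, where the
#' first factor converts Pa to kg m-3 and the second converts mol m-2 s-1
#' to m s-1.
#'
#' @param g_tw total conductance to water vapour, mol m-2 s-1.
#' @param t_leaf leaf temperature, K.
#' @param air an [air_state()].
#' @param clamp_negative clamp condensation (negative E) to zero with a
#'   warning (default TRUE).
#' @return Transpiration rate, kg m-2 s-1.
#' @export
transpiration <- function(g_tw, t_leaf, air, clamp_negative = TRUE) {
  stopifnot(all(g_tw >= 0))
  e <- 0.622 * air_density(air) / air$p_atm *
    (eb_constants$gas_constant * t_leaf / air$p_atm) * g_tw *
    (saturation_vapour_pressure(t_leaf) - air_vapour_pressure(air))
  if (clamp_negative && any(e < 0)) {
    warning("transpiration: negative flux (condensation) clamped to 0")
    e <- pmax(e, 0)
  }
  e
}

#' Energy-budget breakdown
#'
#' The four terms of the budget `Rn - C - lambda E = S`, where the storage
#' term S drives the temperature change.  The identity
#' `storage = Rn - C - latent` holds exactly by construction.
#'
#' @inheritParams net_radiation
#' @param air an [air_state()].
#' @param latent latent heat flux lambda E, W m-2.
#' @return A list with `Rn`, `C`, `latent`, `storage` (all W m-2).
#' @export
flux_breakdown <- function(props, I_s, t_k, air, L_d = 0, latent = 0) {
  rn <- net_radiation(props, I_s, t_k, L_d)
  cc <- sensible_heat(props, t_k, air)
  list(Rn = rn, C = cc, latent = latent, storage = rn - cc - latent)
}

# latent heat flux (W m-2) of an object at temperature T1 and time t,
# given its stomatal/pore conductance (mol m-2 s-1).  Internal workhorse
# for the ODE right-hand sides; condensation is clamped silently here
# (the exported transpiration() warns).
latent_flux <- function(t1, t, gs, env, props, ratio_wh = 1.08,
                        latent_scale = 1) {
  if (props$transpiring_sides == 0 || gs <= 0) return(0)
  air <- env_air_at(env, t)
  g_bw <- gbh_to_gbw(props$g_bh, air$t_air, air$p_atm,
                     sides = props$transpiring_sides, ratio_wh = ratio_wh)
  g_tw <- total_conductance(g_bw, gs)
  e <- transpiration(g_tw, t1, air, clamp_negative = FALSE)
  latent_scale * latent_heat(t1) * max(e, 0)
}

#' Reference-differenced temperature derivative
#'
#' The right-hand side of the differenced energy-balance ODE: the rate of
#' change of the target object's temperature written relative to the
#' budget of a non-transpiring reference in the same thermal environment,
#' so that the shared longwave input cancels:
#'
#' \deqn{\frac{dT_1}{dt} = \frac{k_2 \dot T_2
#'   + (\alpha_1 I_{s1} - \alpha_2 I_{s2})
#'   + 2\theta(\epsilon_2 T_2^4 - \epsilon_1 T_1^4)
#'   + 2\rho C_s\left[g_{bh2}(T_2 - T_{air}) - g_{bh1}(T_1 - T_{air})\right]
#'   - \lambda E_1}{k_1}}
#'
#' @param t1 current target temperature, K.
#' @param t time, s (inside every signal's domain).
#' @param ref_signal a [smooth_signal()] of the reference temperature (K).
#' @param env an [env_signals()] object.
#' @param props1 target object ([thermal_object()]).
#' @param props2 reference object; must be non-transpiring.
#' @param latent1 latent heat flux of the target, W m-2.
#' @return dT1/dt, K s-1.
#' @export
differenced_rhs <- function(t1, t, ref_signal, env, props1, props2,
                            latent1 = 0) {
  if (props2$transpiring_sides != 0)
    stop("differenced_rhs: the reference must be non-transpiring")
  air <- env_air_at(env, t)
  rho <- air_density(air)
  cs <- humid_air_specific_heat(air)
  th <- eb_constants$stefan_boltzmann
  t2 <- ref_signal$value(t)
  dt2 <- ref_signal$deriv(t)
  is1 <- env_is_at(env, t, props1$light_fraction)
  is2 <- env_is_at(env, t, props2$light_fraction)
  (props2$k * dt2 +
     (props1$alpha * is1 - props2$alpha * is2) +
     2 * th * (props2$epsilon * t2^4 - props1$epsilon * t1^4) +
     2 * rho * cs * (props2$g_bh * (t2 - air$t_air) -
                       props1$g_bh * (t1 - air$t_air)) -
     latent1) / props1$k
}

#' Single-object energy-budget temperature derivative
#'
#' `dT/dt = (Rn - C - lambda E) / k` for one object in a known radiation
#' environment.  Used by the forward simulator, and as the algebraic
#' oracle against which the differenced form is checked.
#'
#' @inheritParams differenced_rhs
#' @param props a [thermal_object()].
#' @param L_d longwave received from the surroundings, W m-2.
#' @param latent latent heat flux, W m-2.
#' @return dT/dt, K s-1.
#' @export
full_budget_rhs <- function(t1, t, props, env, L_d = 0, latent = 0) {
  air <- env_air_at(env, t)
  is <- env_is_at(env, t, props$light_fraction)
  fb <- flux_breakdown(props, is, t1, air, L_d, latent)
  fb$storage / props$k
}

#' Steady-state temperature of an object
#'
#' Root of `Rn - C - lambda E = 0` under a constant environment, found by
#' bisection.  Serves as the analytic end point against which terminal
#' temperatures of dynamic integrations are checked.
#'
#' @param props a [thermal_object()].
#' @param air an [air_state()] (scalar fields).
#' @param I_s incident shortwave at the object's site, W m-2.
#' @param L_d received longwave, W m-2.
#' @param gs stomatal/pore conductance, mol m-2 s-1 (0 for a dry object).
#' @param ratio_wh,latent_scale see [predict_temperature()].
#' @return Equilibrium temperature, K.
#' @export
steady_state_temperature <- function(props, air, I_s, L_d = NULL, gs = 0,
                                     ratio_wh = 1.08, latent_scale = 1) {
  if (is.null(L_d))
    L_d <- 2 * eb_constants$stefan_boltzmann * air$t_air^4
  f <- function(tt) {
    lat <- if (props$transpiring_sides > 0 && gs > 0) {
      g_bw <- gbh_to_gbw(props$g_bh, air$t_air, air$p_atm,
                         sides = props$transpiring_sides,
                         ratio_wh = ratio_wh)
      g_tw <- total_conductance(g_bw, gs)
      latent_scale * latent_heat(tt) *
        max(transpiration(g_tw, tt, air, clamp_negative = FALSE), 0)
    } else 0
    net_radiation(props, I_s, tt, L_d) - sensible_heat(props, tt, air) - lat
  }
  lo <- max(air$t_air - 40, 231)
  hi <- min(air$t_air + 60, 339)
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Solver settings for the stiff integrator
#'
#' @param rtol,atol relative/absolute tolerances of the variable-step
#'   integrator (atol in K).
#' @param max_step maximum internal step, s; keeps the solver from
#'   stepping across light switches.
#' @param forcing_dt grid spacing used to tabulate the driver signals for
#'   the compiled right-hand side, s.
#' @param method deSolve method name (default `"bdf"`, an implicit
#'   backward-differentiation scheme suited to this stiff system).
#' @return A list of class `solver_control`.
#' @export
solver_control <- function(rtol = 1e-6, atol = 1e-8, max_step = 5,
                           forcing_dt = 1, method = "bdf") {
  structure(list(rtol = rtol, atol = atol, max_step = max_step,
                 forcing_dt = forcing_dt, method = method),
            class = "solver_control")
}

# ---- compiled-model plumbing -------------------------------------------

# grid with extra nodes hugging each light switch so linear interpolation
# of the tabulated drivers preserves the step
forcing_grid <- function(domain, switch_times, dt) {
  g <- seq(domain[1], domain[2], by = dt)
  if (g[length(g)] < domain[2]) g <- c(g, domain[2])
  ex <- c(switch_times - 1e-6, switch_times)
  ex <- ex[ex > domain[1] & ex < domain[2]]
  sort(unique(c(g, ex)))
}

# tabulate the twelve driver forcings of the compiled RHS.  Each channel
# gets a grid matched to its variability: the piecewise-constant
# irradiances need nodes only around the switches, the reference
# temperature and its derivative need a fine grid, and the slowly
# drifting air properties a coarse one.
build_forcings <- function(ref_signals, env, props1, ref_props, domain,
                           control) {
  sw <- env$switch_times
  is_grid <- forcing_grid(domain, sw, domain[2] - domain[1])
  ref_grid <- forcing_grid(domain, sw, control$forcing_dt)
  air_grid <- forcing_grid(domain, sw, max(control$forcing_dt * 6, 120))
  air <- env_air_at(env, air_grid)
  forc <- list(
    cbind(is_grid, env_is_at(env, is_grid, props1$light_fraction)),
    cbind(air_grid, air$t_air),
    cbind(air_grid, air_density(air)),
    cbind(air_grid, humid_air_specific_heat(air)),
    cbind(air_grid, air_vapour_pressure(air)),
    cbind(air_grid, air$p_atm)
  )
  dummy <- cbind(domain, c(0, 0))
  for (r in 1:2) {
    if (r <= length(ref_signals)) {
      forc[[6 + 3 * r - 2]] <-
        cbind(is_grid, env_is_at(env, is_grid,
                                 ref_props[[r]]$light_fraction))
      forc[[6 + 3 * r - 1]] <- cbind(ref_grid,
                                     ref_signals[[r]]$value(ref_grid))
      forc[[6 + 3 * r]] <- cbind(ref_grid,
                                 ref_signals[[r]]$deriv(ref_grid))
    } else {
      forc[[6 + 3 * r - 2]] <- dummy
      forc[[6 + 3 * r - 1]] <- dummy
      forc[[6 + 3 * r]] <- dummy
    }
  }
  forc
}

# parameter vector of the compiled RHS (layout mirrored in
# src/leafeb_ode.c); ref_props is a list of 1 or 2 thermal_objects
build_parms <- function(props1, ref_props, conductance, schedule, domain,
                        gs_clamp, ratio_wh, latent_scale) {
  gs_mode <- 0; gs_fix <- 0
  t_on <- domain[2] + 1e6; t_off <- domain[2] + 2e6
  g1 <- g2 <- g3 <- 0; phi_i <- phi_d <- 0; tau_i <- tau_d <- 1; s_l <- 0
  if (inherits(conductance, "stomatal_kinetics")) {
    if (is.null(schedule))
      stop("a light_schedule is required with stomatal_kinetics")
    np <- length(schedule$levels)
    st <- schedule$switch_times
    g1 <- conductance$g1; g2 <- conductance$g2; g3 <- conductance$g3
    phi_i <- conductance$phi_i; tau_i <- conductance$tau_i
    phi_d <- conductance$phi_d; tau_d <- conductance$tau_d
    s_l <- conductance$s_l
    if (np == 1) { gs_mode <- 0; gs_fix <- g1 }
    else {
      gs_mode <- 1
      t_on <- st[2]
      t_off <- if (np >= 3) st[3] else domain[2] + 1e6
    }
  } else {
    stopifnot(is.numeric(conductance), length(conductance) == 1,
              conductance >= 0)
    gs_fix <- conductance
  }
  sides <- max(props1$transpiring_sides, 0)
  refp <- numeric(8)
  for (r in seq_along(ref_props)) {
    if (ref_props[[r]]$transpiring_sides != 0)
      stop("the reference must be non-transpiring")
    refp[(4 * r - 3):(4 * r)] <- c(ref_props[[r]]$k, ref_props[[r]]$alpha,
                                   ref_props[[r]]$epsilon,
                                   ref_props[[r]]$g_bh)
  }
  c(props1$k, props1$alpha, props1$epsilon, props1$g_bh,
    if (sides > 0) latent_scale else 0, max(sides, 1), ratio_wh,
    gs_mode, gs_fix, gs_clamp, t_on, t_off,
    g1, g2, g3, phi_i, tau_i, phi_d, tau_d, s_l,
    length(ref_props), refp)
}

# run the compiled differenced model; parms/forcings prebuilt (MCMC path).
# y0 carries one initial value per reference-driven trajectory.
integrate_compiled <- function(parms, forcings, times, y0, control) {
  out <- deSolve::ode(
    y = setNames(y0, paste0("T1.", seq_along(y0))), times = times,
    func = "derivs_diff", parms = parms, dllname = "leafeb",
    initfunc = "initmod_diff", initforc = "initforc_diff",
    forcings = forcings, fcontrol = list(method = "linear", rule = 2),
    method = control$method, rtol = control$rtol, atol = control$atol,
    hmax = control$max_step, maxsteps = 10000, nout = 1, outnames = "gs")
  if (attr(out, "istate")[1] < 0)
    stop("ODE solver failed; last successful time = ",
         signif(max(out[, "time"]), 8), " s")
  out
}

#' Predict an object's temperature kinetics from a reference
#'
#' Integrates the reference-differenced energy-balance ODE from an initial
#' temperature, with the latent term computed at every step from either a
#' fixed conductance or the dynamic stomatal model, and returns the
#' predicted temperature on the requested timestamps.
#'
#' The default engine evaluates a compiled right-hand side with the driver
#' signals tabulated on a fine grid (`control$forcing_dt`); the `"R"`
#' engine evaluates [differenced_rhs()] directly through the smooth-signal
#' objects and exists for validation and experimentation.
#'
#' @param props1 target object ([thermal_object()]).
#' @param props2 reference object (non-transpiring).
#' @param ref reference temperature: an [eb_trace()] (smoothed internally)
#'   or a ready [smooth_signal()].
#' @param env an [environment_trace()] or [env_signals()].
#' @param conductance either a single fixed conductance (mol m-2 s-1) or a
#'   [stomatal_kinetics()] object (then `schedule` is required).
#' @param schedule a [light_schedule()]; defaults to the schedule recorded
#'   in `env` when that is an environment trace.
#' @param t1_0 initial temperature, K; defaults to the reference value at
#'   the first output time.
#' @param times output timestamps, s; defaults to the reference trace's.
#' @param engine `"compiled"` (default) or `"R"`.
#' @param control a [solver_control()].
#' @param gs_clamp lower clamp applied to the modelled stomatal
#'   conductance before it enters the series-conductance chain,
#'   mol m-2 s-1.
#' @param ratio_wh water-to-heat diffusivity correction (see
#'   [gbh_to_gbw()]).
#' @param latent_scale multiplier on the latent term (1 under the
#'   aggregated-conductance convention; 2 if per-side conductances are
#'   supplied for an object transpiring from both faces).
#' @return An [eb_trace()] of the predicted temperature with the modelled
#'   conductance attached as attribute `"gs"`.
#' @export
predict_temperature <- function(props1, props2, ref, env, conductance = 0,
                                schedule = NULL, t1_0 = NULL, times = NULL,
                                engine = c("compiled", "R"),
                                control = solver_control(),
                                gs_clamp = 1e-6, ratio_wh = 1.08,
                                latent_scale = 1) {
  engine <- match.arg(engine)
  if (inherits(env, "env_trace")) {
    if (is.null(schedule) && inherits(conductance, "stomatal_kinetics"))
      schedule <- env_light_schedule(env)
    env <- env_signals(env)
  }
  stopifnot(inherits(env, "env_signals"))
  if (inherits(ref, "eb_trace") || is.data.frame(ref)) {
    if (is.null(times)) times <- as_eb_trace(ref)$time
    ref <- smooth_signal(ref, breaks = env$switch_times)
  }
  stopifnot(inherits(ref, "smooth_signal"))
  if (is.null(times)) stop("output times are required")
  dom <- c(max(ref$domain[1], env$domain[1]),
           min(ref$domain[2], env$domain[2]))
  if (any(times < dom[1] - 1e-9) || any(times > dom[2] + 1e-9))
    stop("requested times outside the common signal domain [",
         dom[1], ", ", dom[2], "] s")
  if (is.null(t1_0)) t1_0 <- ref$value(times[1])

  if (engine == "compiled") {
    parms <- build_parms(props1, list(props2), conductance, schedule, dom,
                         gs_clamp, ratio_wh, latent_scale)
    forc <- build_forcings(list(ref), env, props1, list(props2),
                           c(times[1], times[length(times)]), control)
    out <- integrate_compiled(parms, forc, times, t1_0, control)
  } else {
    gs_fun <- make_gs_fun(conductance, schedule, gs_clamp)
    rhs <- function(t, y, p) {
      t <- min(max(t, dom[1]), dom[2])  # lsoda may probe past the ends
      gs <- gs_fun(t)
      lat <- latent_flux(y[1], t, gs, env, props1, ratio_wh, latent_scale)
      list(differenced_rhs(y[1], t, ref, env, props1, props2, lat), gs = gs)
    }
    out <- deSolve::ode(y = c(T1 = t1_0), times = times, func = rhs,
                        parms = NULL, method = "lsoda",
                        rtol = control$rtol, atol = control$atol,
                        hmax = control$max_step)
    if (attr(out, "istate")[1] < 0)
      stop("ODE solver failed; last successful time = ",
           signif(max(out[, "time"]), 8), " s")
  }
  res <- eb_trace(out[, 1], out[, 2], "temperature")
  attr(res, "gs") <- out[, "gs"]
  res
}

# conductance-as-function-of-time closure shared by the R engine and the
# forward simulator
make_gs_fun <- function(conductance, schedule, gs_clamp = 1e-6) {
  if (inherits(conductance, "stomatal_kinetics")) {
    if (is.null(schedule))
      stop("a light_schedule is required with stomatal_kinetics")
    function(t) {
      # the adaptive solver may probe marginally outside the span
      st <- schedule$switch_times
      t <- pmin(pmax(t, st[1]), st[length(st)])
      pmax(gs_schedule(t, conductance, schedule), gs_clamp)
    }
  } else {
    stopifnot(is.numeric(conductance), length(conductance) == 1)
    function(t) conductance
  }
}
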