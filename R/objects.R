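#' Thermal and optical description of a flat object
#'
#' Everything the energy-balance model needs to know about a leaf,
#' aluminium reference or replica plate.
#'
#' @param alpha shortwave absorbance, in \[0, 1\].
#' @param epsilon longwave emissivity, in \[0, 1\].
#' @param k areal heat capacity, J m-2 K-1 (> 0): the energy per unit
#'   (projected) area needed to change the object's temperature by 1 K,
#'   i.e. density x specific heat x thickness.
#' @param g_bh one-sided boundary-layer conductance to heat, m s-1 (>= 0).
#' @param transpiring_sides 0 (dry reference), 1 (replica with one wet
#'   face) or 2 (amphistomatous leaf).  Determines how many boundary
#'   layers aggregate into the vapour conductance; the latent term itself
#'   enters the budget once, through the series conductance chain.
#' @param light_fraction fraction of the nominal incident shortwave
#'   reaching this object's position (objects at different spots in the
#'   imaging area can receive different irradiance), default 1.
#' @return An object of class `thermal_object`.
#' @export
thermal_object <- function(alpha, epsilon, k, g_bh = 0,
                           transpiring_sides = 0, light_fraction = 1) {
  stopifnot(alpha >= 0, alpha <= 1, epsilon >= 0, epsilon <= 1, k > 0,
            g_bh >= 0, transpiring_sides %in% 0:2, light_fraction >= 0)
  structure(list(alpha = alpha, epsilon = epsilon, k = k, g_bh = g_bh,
                 transpiring_sides = transpiring_sides,
                 light_fraction = light_fraction),
            class = "thermal_object")
}

#' Environmental trace
#'
#' Synchronized environmental drivers on a common time grid, in internal
#' units (K, fraction, Pa).  The PPFD channel is treated as a controlled
#' input: it is interpolated as a step function, never spline-smoothed.
#'
#' @param time sample times, s.
#' @param ppfd photosynthetic photon flux density, umol m-2 s-1.
#' @param t_air air temperature, K.
#' @param rh relative humidity, fraction.
#' @param p_atm atmospheric pressure, Pa.
#' @param ppfd_factor radiation conversion factor, J umol-1.
#' @return A data frame of class `env_trace`.
#' @export
environment_trace <- function(time, ppfd, t_air, rh, p_atm = 101325,
                              ppfd_factor = 0.22) {
  n <- length(time)
  stopifnot(n >= 4, !is.unsorted(time, strictly = TRUE))
  df <- data.frame(time = time, ppfd = rep_len(ppfd, n),
                   t_air = rep_len(t_air, n), rh = rep_len(rh, n),
                   p_atm = rep_len(p_atm, n))
  air_state(df$t_air, df$rh, df$p_atm)   # range validation
  if (any(df$ppfd < 0)) stop("environment_trace: negative PPFD")
  structure(df, ppfd_factor = ppfd_factor,
            class = c("env_trace", "data.frame"))
}

#' Turn an environmental trace into smooth driver signals
#'
#' Air temperature, humidity and pressure are smoothed into differentiable
#' signals (measured channels carry sensor noise); PPFD is kept as an
#' exact step function of time (it is a known control signal, and
#' smoothing a step would ring).  With `exact = TRUE` all channels are
#' linearly interpolated without smoothing -- the forward simulator uses
#' this because its drivers are known functions, not measurements.
#'
#' @param env an [environment_trace()].
#' @param smoothing optional `spar` passed to [smooth_signal()].
#' @param exact logical; skip smoothing entirely.
#' @return A list of class `env_signals` with elements `ppfd` (function of
#'   t), `t_air`, `rh`, `p_atm` (smooth signals), `switch_times` (times
#'   where PPFD changes level), `ppfd_factor` and `domain`.
#' @export
env_signals <- function(env, smoothing = NULL, exact = FALSE) {
  stopifnot(inherits(env, "env_trace"))
  tt <- env$time
  ppfd_fun <- stats::approxfun(tt, env$ppfd, method = "constant",
                               rule = 2, f = 0)
  jumps <- which(diff(env$ppfd) != 0)
  mk <- function(col, channel) {
    if (exact || stats::sd(env[[col]]) == 0)
      exact_signal(tt, env[[col]], channel)
    else
      smooth_signal(eb_trace(tt, env[[col]], channel),
                    smoothing = smoothing,
                    breaks = if (length(jumps)) tt[jumps + 1])
  }
  structure(list(
    ppfd = ppfd_fun,
    t_air = mk("t_air", "t_air"),
    rh = mk("rh", "rh"),
    p_atm = mk("p_atm", "p_atm"),
    switch_times = if (length(jumps)) tt[jumps + 1] else numeric(0),
    ppfd_factor = attr(env, "ppfd_factor"),
    domain = range(tt)
  ), class = "env_signals")
}

# air state at time t from env signals
env_air_at <- function(es, t) {
  air_state(es$t_air$value(t), pmin(pmax(es$rh$value(t), 0), 1),
            es$p_atm$value(t))
}

# incident shortwave (W m-2) at time t at an object's site
env_is_at <- function(es, t, light_fraction = 1) {
  ppfd_to_shortwave(pmax(es$ppfd(t), 0), es$ppfd_factor) * light_fraction
}

#' Infer the light schedule recorded in an environmental trace
#'
#' @param env an [environment_trace()].
#' @return A [light_schedule()] spanning the trace.
#' @export
env_light_schedule <- function(env) {
  stopifnot(inherits(env, "env_trace"))
  jumps <- which(diff(env$ppfd) != 0)
  st <- c(env$time[1], env$time[jumps + 1], env$time[nrow(env)])
  light_schedule(st, env$ppfd[c(1, jumps + 1)])
}
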