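#' Stomatal kinetics parameter set
#'
#' Parameters of the dynamic stomatal-conductance model over a
#' dark/light/dark protocol: steady-state targets for each phase, lags and
#' time constants for increases and decreases, and the slope of the slow
#' linear drift of conductance during the light phase.
#'
#' @param g1,g2,g3 steady-state conductance targets for the initial dark,
#'   light and final dark phases, mol m-2 s-1 (>= 0).
#' @param phi_i,phi_d time lag for an increase / decrease, s.
#' @param tau_i,tau_d time constant for an increase / decrease, s (> 0).
#' @param s_l slope of the linear drift during the light phase,
#'   mol m-2 s-2.
#' @return An object of class `stomatal_kinetics`.
#' @export
stomatal_kinetics <- function(g1 = 0.05, g2 = 0.5, g3 = 0.025,
                              phi_i = 150, tau_i = 300,
                              phi_d = 150, tau_d = 600, s_l = 0) {
  stopifnot(g1 >= 0, g2 >= 0, g3 >= 0, tau_i > 0, tau_d > 0,
            is.finite(phi_i), is.finite(phi_d), is.finite(s_l))
  structure(list(g1 = g1, g2 = g2, g3 = g3, phi_i = phi_i, tau_i = tau_i,
                 phi_d = phi_d, tau_d = tau_d, s_l = s_l),
            class = "stomatal_kinetics")
}

#' Light schedule
#'
#' Piecewise-constant light protocol: `levels[i]` applies on
#' `[switch_times[i], switch_times[i + 1])`, with `switch_times` of length
#' `length(levels) + 1` covering the experiment span.
#'
#' @param switch_times strictly increasing boundaries, s (first element is
#'   the experiment start).
#' @param levels PPFD per interval, umol m-2 s-1.
#' @return An object of class `light_schedule`.
#' @export
light_schedule <- function(switch_times, levels) {
  stopifnot(length(switch_times) == length(levels) + 1,
            length(levels) >= 1, !is.unsorted(switch_times, strictly = TRUE))
  structure(list(switch_times = as.numeric(switch_times),
                 levels = as.numeric(levels)),
            class = "light_schedule")
}

#' Sigmoidal (rescaled Gompertz) conductance response to a light step
#'
#' Closed-form solution of the dynamic stomatal model for a step change:
#' a Gompertz double exponential with lag `phi` and time constant `tau`,
#' rescaled so that `gs(0) = g0` holds exactly even for positive `phi`,
#' plus an optional linear drift of the target:
#'
#' \deqn{g_s(t) = (G + s_l t - g_0)\,
#'   \frac{e^{-e^{(\phi-t)/\tau}} - e^{-e^{\phi/\tau}}}
#'        {1 - e^{-e^{\phi/\tau}}} + g_0}
#'
#' For strongly negative `phi` the rescaling becomes the exponential
#' relaxation \eqn{1 - e^{-t/\tau}} (its analytic limit), which is used
#' when the denominator underflows.
#'
#' @param t time since the step, s (>= 0); may be a vector.
#' @param g0 conductance at t = 0, mol m-2 s-1.
#' @param G steady-state target, mol m-2 s-1.
#' @param tau time constant, s (> 0).
#' @param phi time lag, s.
#' @param s_l linear drift of the target, mol m-2 s-2.
#' @return Conductance at `t`, mol m-2 s-1 (clamped at >= 0).
#' @export
gs_sigmoid <- function(t, g0, G, tau, phi, s_l = 0) {
  if (tau <= 0) stop("gs_sigmoid: tau must be > 0, got ", tau)
  e0 <- exp(-exp(phi / tau))
  a <- if (1 - e0 < 1e-12) {
    1 - exp(-t / tau)          # phi -> -inf limit of the rescaled form
  } else {
    (exp(-exp((phi - t) / tau)) - e0) / (1 - e0)
  }
  pmax((G + s_l * t - g0) * a + g0, 0)
}

#' Stomatal conductance over a full light schedule
#'
#' Evaluates the sigmoidal response piecewise over the schedule.  Within
#' each phase the initial value `g0` is the conductance reached at the end
#' of the previous phase (continuity), the target is that phase's
#' steady-state parameter (`g1`, `g2`, `g3`, recycled in order), the
#' (lag, time constant) pair is chosen by the direction of the response
#' (target above or below `g0`), and the drift `s_l` acts only during lit
#' phases.  The first phase starts at its own target, so a dark baseline
#' is flat.
#'
#' @param t evaluation times, s, inside the schedule span.
#' @param params a [stomatal_kinetics()] object.
#' @param schedule a [light_schedule()] object (up to 3 intervals,
#'   matching the three phase targets).
#' @return Conductance at `t`, mol m-2 s-1.
#' @export
gs_schedule <- function(t, params, schedule) {
  stopifnot(inherits(params, "stomatal_kinetics"),
            inherits(schedule, "light_schedule"))
  st <- schedule$switch_times
  np <- length(schedule$levels)
  if (np > 3) stop("gs_schedule: at most 3 intervals are supported")
  if (any(t < st[1] - 1e-9) || any(t > st[np + 1] + 1e-9))
    stop("gs_schedule: t outside the schedule span [", st[1], ", ",
         st[np + 1], "]")
  targets <- c(params$g1, params$g2, params$g3)[seq_len(np)]
  # propagate phase-start values
  g0s <- numeric(np)
  g0s[1] <- targets[1]
  phase_eval <- function(tl, g0, G, lit) {
    up <- G >= g0
    gs_sigmoid(tl, g0, G,
               tau = if (up) params$tau_i else params$tau_d,
               phi = if (up) params$phi_i else params$phi_d,
               s_l = if (lit) params$s_l else 0)
  }
  if (np > 1) for (p in 2:np) {
    g0s[p] <- phase_eval(st[p] - st[p - 1], g0s[p - 1], targets[p - 1],
                         schedule$levels[p - 1] > 0)
  }
  out <- numeric(length(t))
  idx <- pmin(findInterval(pmax(t, st[1]), st, rightmost.closed = TRUE), np)
  for (p in unique(idx)) {
    sel <- idx == p
    out[sel] <- phase_eval(t[sel] - st[p], g0s[p], targets[p],
                           schedule$levels[p] > 0)
  }
  out
}
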