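#' Pore geometry of a perforated replica membrane
#'
#' @param diameter pore diameter, m.
#' @param depth pore depth (membrane thickness), m.
#' @param density pore areal density, pores m-2.  Use
#'   `per_inch2_to_per_m2()` for sheet specifications quoted per square
#'   inch.
#' @return An object of class `pore_geometry`.
#' @export
pore_geometry <- function(diameter, depth, density) {
  stopifnot(diameter > 0, depth > 0, density >= 0)
  if (diameter >= 1 / sqrt(density))
    stop("pore_geometry: pore diameter exceeds the pitch implied by the ",
         "density")
  structure(list(diameter = diameter, depth = depth, density = density),
            class = "pore_geometry")
}

#' @rdname pore_geometry
#' @param n pores per square inch.
#' @export
per_inch2_to_per_m2 <- function(n) n / 0.0254^2

# binary diffusivity of water vapour in air, m2 s-1, with standard
# temperature/pressure scaling around the 20 degC reference value
diffusivity_wv <- function(t_k, p = 101325, d0 = 2.42e-5) {
  d0 * (t_k / 293.15)^1.75 * (101325 / p)
}

#' Diffusive conductance of a perforated membrane
#'
#' Water-vapour conductance of an array of cylindrical pores with a
#' single-end correction: each pore behaves as a tube of length
#' `depth + pi r / 4`, the added length being the equivalent-length form
#' of the half-space disk access resistance at the open end.
#'
#' \deqn{g = n \, D_{wv}(T, P) \, \frac{\pi r^2}{depth + \pi r / 4} \,
#'       \frac{P}{R T}}
#'
#' @param geom a [pore_geometry()].
#' @param t_k temperature, K.
#' @param p pressure, Pa.
#' @return Conductance in molar units, mol m-2 s-1.
#' @examples
#' g <- pore_conductance(
#'   pore_geometry(0.5e-3, 40e-6, per_inch2_to_per_m2(160)))
#' g  # ~0.207 mol m-2 s-1
#' @export
pore_conductance <- function(geom, t_k = 293.15, p = 101325) {
  stopifnot(inherits(geom, "pore_geometry"))
  r <- geom$diameter / 2
  geom$density * diffusivity_wv(t_k, p) * pi * r^2 /
    (geom$depth + pi * r / 4) * molar_density(t_k, p)
}

#' Boundary-layer conductance from a black/white reference pair
#'
#' Two references cut from the same material (shared areal heat capacity)
#' but with different shortwave absorbances heat differently under light;
#' the size of the temperature contrast is governed by how efficiently
#' both shed heat to the air.  This routine finds the single heat
#' conductance `g_bh` that makes the differenced model, driven by the
#' black reference, reproduce the observed white-reference kinetics in the
#' least-squares sense.  A constant `g_bh` over the record is assumed.
#'
#' @param black,white observed reference temperature traces
#'   ([eb_trace()], K).
#' @param env an [environment_trace()] or [env_signals()].
#' @param props_b,props_w reference properties ([thermal_object()]); their
#'   `g_bh` fields are ignored (that is the unknown).
#' @param interval search interval for `g_bh`, m s-1.
#' @param control a [solver_control()].
#' @return A list with `g_bh` (m s-1), `rmse` (K) and `n` (observations
#'   used).
#' @export
estimate_gbh <- function(black, white, env, props_b, props_w,
                         interval = c(1e-4, 0.2),
                         control = solver_control()) {
  black <- as_eb_trace(black); white <- as_eb_trace(white)
  t0 <- max(black$time[1], white$time[1])
  t1 <- min(black$time[nrow(black)], white$time[nrow(white)])
  if (t1 <= t0) stop("estimate_gbh: traces do not overlap in time")
  if (inherits(env, "env_trace")) env <- env_signals(env)
  ref <- smooth_signal(black, breaks = env$switch_times)
  wsig <- smooth_signal(white, breaks = env$switch_times)
  obs <- white[white$time >= t0 & white$time <= t1, ]
  contrast <- max(abs(ref$value(obs$time) - wsig$value(obs$time)))
  noise <- max(ref$residual_sd, wsig$residual_sd, 1e-4)
  if (contrast < 5 * noise)
    stop("estimate_gbh: no usable temperature contrast between the ",
         "references (max |T_b - T_w| = ", signif(contrast, 3),
         " K < 5 x noise sd)")
  sse <- function(gbh) {
    pw <- props_w; pw$g_bh <- gbh
    pb <- props_b; pb$g_bh <- gbh
    pred <- predict_temperature(pw, pb, ref, env, conductance = 0,
                                t1_0 = wsig$value(obs$time[1]),
                                times = obs$time, control = control)
    sum((pred$value - obs$value)^2)
  }
  opt <- stats::optimize(sse, interval, tol = 1e-7)
  list(g_bh = opt$minimum, rmse = sqrt(opt$objective / nrow(obs)),
       n = nrow(obs))
}
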