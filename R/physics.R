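#' Physical constants
#'
#' Stefan--Boltzmann constant (`stefan_boltzmann`, W m-2 K-4) and the molar
#' gas constant (`gas_constant`, m3 Pa K-1 mol-1), CODATA values.
#'
#' @format A named list with elements `stefan_boltzmann` and `gas_constant`.
#' @export
eb_constants <- list(
  stefan_boltzmann = 5.670374419e-8,
  gas_constant     = 8.31446
)

# molar masses used for moist-air density (kg mol-1)
.M_DRY <- 0.0289647
.M_VAP <- 0.01801528

#' Air state
#'
#' Bundle of air temperature, relative humidity and atmospheric pressure.
#' All fields may be vectors of equal length (or length one, recycled).
#'
#' @param t_air air temperature, K; must lie in (230, 340).
#' @param rh relative humidity as a fraction in \[0, 1\].
#' @param p_atm atmospheric pressure, Pa; must lie in (5e4, 1.2e5).
#' @return An object of class `air_state`.
#' @examples
#' air_state(293.15, 0.5)
#' @export
air_state <- function(t_air, rh = 0.5, p_atm = 101325) {
  n <- max(length(t_air), length(rh), length(p_atm))
  t_air <- rep_len(t_air, n); rh <- rep_len(rh, n); p_atm <- rep_len(p_atm, n)
  if (any(!is.finite(t_air)) || any(t_air <= 230) || any(t_air >= 340))
    stop("air_state: t_air out of range (230, 340) K: ",
         paste(signif(t_air[t_air <= 230 | t_air >= 340 | !is.finite(t_air)], 6),
               collapse = ", "))
  if (any(rh < 0) || any(rh > 1))
    stop("air_state: rh must be a fraction in [0, 1], got ",
         paste(signif(rh[rh < 0 | rh > 1], 6), collapse = ", "))
  if (any(p_atm <= 5e4) || any(p_atm >= 1.2e5))
    stop("air_state: p_atm out of range (5e4, 1.2e5) Pa")
  structure(list(t_air = t_air, rh = rh, p_atm = p_atm), class = "air_state")
}

#' Saturation vapour pressure of water over a plane surface
#'
#' Buck (1981) formulation, valid over liquid water for the temperature
#' range relevant to leaf work (roughly -40 to 60 degC).
#'
#' @param t_k temperature, K; must lie in (230, 340).
#' @return Saturation vapour pressure, Pa.
#' @examples
#' saturation_vapour_pressure(293.15)  # ~2338 Pa at 20 degC
#' @export
saturation_vapour_pressure <- function(t_k) {
  if (any(!is.finite(t_k)) || any(t_k <= 230) || any(t_k >= 340))
    stop("saturation_vapour_pressure: temperature out of range (230, 340) K: ",
         paste(signif(t_k[!is.finite(t_k) | t_k <= 230 | t_k >= 340], 6),
               collapse = ", "))
  tc <- t_k - 273.15
  611.21 * exp((18.678 - tc / 234.5) * tc / (257.14 + tc))
}

#' Actual vapour pressure of air
#'
#' @param air an [air_state()].
#' @return Vapour pressure e_a = RH * es(T_air), Pa.
#' @export
air_vapour_pressure <- function(air) {
  stopifnot(inherits(air, "air_state"))
  air$rh * saturation_vapour_pressure(air$t_air)
}

#' Density of (moist) air
#'
#' Ideal-gas mixture of dry air and water vapour via partial pressures.
#'
#' @param air an [air_state()].
#' @return Air density, kg m-3.
#' @export
air_density <- function(air) {
  stopifnot(inherits(air, "air_state"))
  ea <- air_vapour_pressure(air)
  ((air$p_atm - ea) * .M_DRY + ea * .M_VAP) /
    (eb_constants$gas_constant * air$t_air)
}

#' Specific heat capacity of humid air
#'
#' Mass-weighted mixture of dry air (1005 J kg-1 K-1) and water vapour
#' (1860 J kg-1 K-1), with the specific humidity computed from the vapour
#' partial pressure.
#'
#' @param air an [air_state()].
#' @return Specific heat capacity, J kg-1 K-1.
#' @export
humid_air_specific_heat <- function(air) {
  stopifnot(inherits(air, "air_state"))
  ea <- air_vapour_pressure(air)
  q <- 0.622 * ea / (air$p_atm - 0.378 * ea)  # specific humidity, kg kg-1
  1005 * (1 - q) + 1860 * q
}

#' Latent heat of vaporisation of water
#'
#' Linear-in-temperature approximation
#' lambda(T) = (2.501 - 0.002361 (T - 273.15)) x 1e6 J kg-1.
#'
#' @param t_k temperature, K; must lie in (230, 340).
#' @return Latent heat, J kg-1.
#' @export
latent_heat <- function(t_k) {
  if (any(!is.finite(t_k)) || any(t_k <= 230) || any(t_k >= 340))
    stop("latent_heat: temperature out of range (230, 340) K")
  (2.501 - 0.002361 * (t_k - 273.15)) * 1e6
}

#' Convert photon flux to shortwave energy flux
#'
#' The conversion factor is source-specific and should be measured with a
#' spectroradiometer for the light source in use; 0.22 J umol-1 is a
#' reasonable default for white LEDs.
#'
#' @param ppfd photosynthetic photon flux density, umol m-2 s-1 (>= 0).
#' @param factor radiation conversion factor, J umol-1 (> 0).
#' @return Shortwave irradiance, W m-2.
#' @export
ppfd_to_shortwave <- function(ppfd, factor = 0.22) {
  if (any(ppfd < 0)) stop("ppfd_to_shortwave: negative PPFD: ",
                          paste(signif(ppfd[ppfd < 0], 6), collapse = ", "))
  if (any(factor <= 0)) stop("ppfd_to_shortwave: factor must be > 0")
  ppfd * factor
}

#' Molar density of an ideal gas
#'
#' The unit bridge P/(R T) converting conductances between m s-1 and
#' mol m-2 s-1.
#'
#' @param t_k temperature, K.
#' @param p pressure, Pa.
#' @return Molar density, mol m-3.
#' @export
molar_density <- function(t_k, p = 101325) {
  stopifnot(all(t_k > 0), all(p > 0))
  p / (eb_constants$gas_constant * t_k)
}

#' Convert a heat boundary-layer conductance to a vapour conductance
#'
#' g_bh (m s-1, one-sided, heat) is converted to g_bw (mol m-2 s-1, water
#' vapour) by aggregating `sides` boundary layers, applying the
#' water-to-heat diffusivity correction and the molar density of air:
#' `g_bw = sides * ratio_wh * g_bh * P/(R T)`.
#'
#' @param g_bh one-sided boundary-layer conductance to heat, m s-1.
#' @param t_k air temperature, K.
#' @param p pressure, Pa.
#' @param sides number of exchanging sides, 1 or 2 (amphistomatous leaf: 2).
#' @param ratio_wh water-to-heat diffusivity correction for laminar
#'   boundary layers (default 1.08, the diffusivity ratio to the 2/3 power).
#' @return Boundary-layer conductance to water vapour, mol m-2 s-1.
#' @examples
#' gbh_to_gbw(0.0143, 293.15)  # ~1.28 mol m-2 s-1
#' @export
gbh_to_gbw <- function(g_bh, t_k, p = 101325, sides = 2, ratio_wh = 1.08) {
  stopifnot(all(g_bh >= 0), sides %in% c(1, 2))
  sides * ratio_wh * g_bh * molar_density(t_k, p)
}
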