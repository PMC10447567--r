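# Pointwise kinetic rate laws. The same expressions act on tank
# concentrations and on every biofilm grid cell; all are homogeneous of
# degree 1 in the particulate concentrations.

#' Monod specific growth rate
#'
#' \eqn{\mu(S_G) = \mu_{max} S_G / (K_M + S_G)}: saturating growth on
#' glucose, half of \eqn{\mu_{max}} at \eqn{S_G = K_M}.
#'
#' @param S_G glucose concentration(s), g/m3, non-negative.
#' @param p a [biofilm_params()] object.
#' @return specific growth rate(s), 1/day.
#' @examples
#' growth_rate(5, biofilm_params())  # half-velocity: 4.8 /d
#' @export
growth_rate <- function(S_G, p = biofilm_params()) {
  if (any(S_G < 0)) stop("glucose concentration must be non-negative")
  p$mu_max * S_G / (p$K_M + S_G)
}

#' Net particulate production rates
#'
#' Live biomass grows at the Monod rate and is converted to dead biomass
#' by first-order disinfection in the local HP concentration:
#' \deqn{R_{X:L} = \mu(S_G) X_L - k_{dis} S_H X_L, \quad
#'       R_{X:D} = k_{dis} S_H X_L.}
#' Killing transfers biomass live to dead without loss, so
#' \eqn{R_{X:L} + R_{X:D}} is the growth term alone.
#'
#' @param X_L,X_D live and dead particulate concentrations, g/m3.
#' @param S_G,S_H glucose and HP concentrations, g/m3.
#' @param p a [biofilm_params()] object.
#' @return list with components `live` and `dead`, g/m3/day. Vectorized.
#' @export
particulate_rates <- function(X_L, X_D, S_G, S_H, p = biofilm_params()) {
  if (any(c(X_L, X_D, S_G, S_H) < 0))
    stop("concentrations must be non-negative")
  kill <- p$k_dis * S_H * X_L
  list(live = growth_rate(S_G, p) * X_L - kill, dead = kill)
}

#' Net solute consumption rates
#'
#' Glucose is consumed by live-biomass growth at yield `Y_GL`; hydrogen
#' peroxide is neutralized (catalase-type, viability-independent) by both
#' live and dead biomass:
#' \deqn{R_{S:G} = -\mu(S_G) X_L / Y_{GL}, \quad
#'       R_{S:H} = -(k_{B:L} X_L + k_{B:D} X_D) S_H.}
#' Both rates are non-positive.
#'
#' @inheritParams particulate_rates
#' @return list with components `glucose` and `hp`, g/m3/day. Vectorized.
#' @export
solute_rates <- function(X_L, X_D, S_G, S_H, p = biofilm_params()) {
  if (any(c(X_L, X_D, S_G, S_H) < 0))
    stop("concentrations must be non-negative")
  if (p$Y_GL <= 0) stop("yield coefficient Y_GL must be positive")
  list(glucose = -growth_rate(S_G, p) * X_L / p$Y_GL,
       hp = -(p$k_B_L * X_L + p$k_B_D * X_D) * S_H)
}

#' Detachment velocity at the biofilm surface
#'
#' Surface erosion speed \eqn{v_{det} = K_{det} L_f^2}: quadratic in the
#' film thickness, which gives a stable balance against growth and sets
#' the untreated steady-state thickness.
#'
#' @param Lf biofilm thickness(es), m, non-negative.
#' @param p a [biofilm_params()] object.
#' @return detachment velocity, m/day.
#' @examples
#' detachment_velocity(150e-6, biofilm_params())  # 2.25e-4 m/d
#' @export
detachment_velocity <- function(Lf, p = biofilm_params()) {
  if (any(Lf < 0)) stop("thickness must be non-negative")
  p$K_det * Lf^2
}
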