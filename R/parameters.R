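# Model parameters and the hydrogen peroxide dosing schedule.
#
# Units are SI-with-days throughout: lengths in m, time in days,
# concentrations in g/m^3, areas in m^2, volumes in m^3. Keeping the
# native units of the parameter table avoids conversion bugs.

.default_params <- list(
  mu_max  = 9.6,      # maximum specific growth rate, 1/d
  K_M     = 5.0,      # Monod half-saturation constant for glucose, g/m^3
  Q       = 1.0,      # flow rate through the tank, m^3/d
  V       = 0.1,      # tank volume, m^3
  A       = 1.0,      # biofilm surface area, m^2
  k_dis   = 0.5,      # disinfection rate coefficient, (g_H/m^3)^-1 d^-1
  Y_GL    = 0.26,     # yield of live biomass on glucose, g_L/g_G
  S_in_G  = 100,      # influent glucose concentration, g/m^3
  k_B_L   = 10,       # HP neutralization coefficient, live biomass
  k_B_D   = 10,       # HP neutralization coefficient, dead biomass
  rho_L   = 2.5e5,    # live biomass density, g/m^3
  rho_D   = 2.5e5,    # dead biomass density, g/m^3
  D_b_G   = 1.3e-5,   # glucose diffusivity in the biofilm, m^2/d
  D_b_H   = 6.52e-5,  # HP diffusivity in the biofilm, m^2/d
  D_aq_G  = 5.2e-5,   # glucose diffusivity in water, m^2/d
  D_aq_H  = 1.09e-4,  # HP diffusivity in water, m^2/d
  L_L     = 1.0e-5,   # mass-transfer boundary-layer thickness, m
  K_det   = 1e4,      # detachment coefficient, 1/(m d)
  Lf0     = 50e-6,    # initial biofilm thickness, m
  X_t0    = c(1.0, 0.0),    # initial tank particulates [live, dead], g/m^3
  S_t0    = c(100.0, 0.0),  # initial tank solutes [glucose, HP], g/m^3
  P_b0    = c(0.08, 0.0),   # initial biofilm volume fractions [live, dead]
  S_b0    = c(0.0, 0.0),    # initial biofilm solutes [glucose, HP], g/m^3
  Nz      = 50L,      # grid cells across the film
  t_final = 100,      # default simulation horizon, d
  rtol    = 1e-6,     # solver relative tolerance
  atol    = 1e-6,     # absolute tolerance on concentrations, g/m^3
  atol_Lf = 1e-10,    # absolute tolerance on the thickness state, m
  Lf_floor = 1e-8,    # thickness floor preventing the 1/Lf singularity, m
  Lf_eradicate = 1e-6 # thickness below which the film counts as eradicated, m
)

.scalar_nonneg <- c(
  "mu_max", "K_M", "Q", "V", "A", "k_dis", "Y_GL", "S_in_G", "k_B_L",
  "k_B_D", "rho_L", "rho_D", "D_b_G", "D_b_H", "D_aq_G", "D_aq_H",
  "L_L", "K_det", "Lf0", "t_final", "rtol", "atol", "atol_Lf",
  "Lf_floor", "Lf_eradicate"
)

#' Model parameters for the biofilm-in-a-tank system
#'
#' Builds the validated parameter set of the hydrogen peroxide / biofilm
#' model. Defaults are the standard base-case values: a glucose-limited
#' biofilm (Monod kinetics, \eqn{\mu_{max}} = 9.6/d, \eqn{K_M} = 5 g/m3)
#' growing on 1 m2 of surface in a 0.1 m3 stirred tank fed at 1 m3/d with
#' 100 g/m3 glucose, first-order disinfection by hydrogen peroxide
#' (\eqn{k_{dis}} = 0.5 per (g/m3) per day), equal catalase-type HP
#' neutralization by live and dead biomass (\eqn{k_{B:L}=k_{B:D}=10}),
#' and quadratic surface detachment (\eqn{K_{det}} = 1e4 /(m d)).
#'
#' Units are m, day and g/m3 throughout. Particulate state is always
#' ordered `[live, dead]` and solute state `[glucose, HP]`.
#'
#' @param ... named overrides of the defaults, e.g. `k_B_D = 0`,
#'   `S_in_G = 16`, `Nz = 200`. Unknown names are an error.
#' @return an object of class `biofilm_params`: a named list with all
#'   rate constants, geometry, diffusivities, initial conditions,
#'   grid size `Nz` and solver settings.
#' @examples
#' p <- biofilm_params()            # base case
#' p_knock <- biofilm_params(k_B_D = 0)  # no neutralization by dead cells
#' @export
biofilm_params <- function(...) {
  over <- list(...)
  if (length(over) > 0 && (is.null(names(over)) || any(names(over) == "")))
    stop("all parameter overrides must be named")
  unknown <- setdiff(names(over), names(.default_params))
  if (length(unknown) > 0)
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p <- utils::modifyList(.default_params, over)
  p$Nz <- as.integer(p$Nz)
  validate_params(p)
  structure(p, class = "biofilm_params")
}

validate_params <- function(p) {
  for (nm in .scalar_nonneg) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0)
      stop("parameter '", nm, "' must be a finite non-negative scalar")
  }
  for (nm in c("X_t0", "S_t0", "P_b0", "S_b0")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 2 || any(!is.finite(v)) || any(v < 0))
      stop("parameter '", nm, "' must be two finite non-negative values [live/glucose, dead/HP]")
  }
  if (p$Y_GL <= 0) stop("yield coefficient Y_GL must be > 0")
  if (p$Nz < 2) stop("Nz must be at least 2")
  if (p$Lf0 <= 0) stop("initial thickness Lf0 must be > 0")
  if (sum(p$P_b0) > 1) stop("initial volume fractions P_b0 must sum to at most 1")
  if (sum(p$P_b0) <= 0) stop("initial volume fractions P_b0 must contain some biomass")
  if (p$V <= 0 || p$Q < 0) stop("tank volume must be positive")
  invisible(p)
}

#' @export
print.biofilm_params <- function(x, ...) {
  cat("Biofilm model parameters (m / day / g m^-3 units)\n")
  cat(sprintf("  growth:      mu_max = %g /d, K_M = %g g/m3, Y_GL = %g\n",
              x$mu_max, x$K_M, x$Y_GL))
  cat(sprintf("  disinfection: k_dis = %g, neutralization k_B_L = %g, k_B_D = %g\n",
              x$k_dis, x$k_B_L, x$k_B_D))
  cat(sprintf("  tank:        Q = %g m3/d, V = %g m3, A = %g m2, S_in_G = %g g/m3\n",
              x$Q, x$V, x$A, x$S_in_G))
  cat(sprintf("  detachment:  K_det = %g /(m d);  initial Lf = %g um\n",
              x$K_det, 1e6 * x$Lf0))
  cat(sprintf("  grid/solver: Nz = %d, t_final = %g d, rtol = %g, atol = %g\n",
              x$Nz, x$t_final, x$rtol, x$atol))
  invisible(x)
}

#' Hydrogen peroxide dosing schedule
#'
#' The influent HP concentration is a piecewise-constant function of
#' time: 0 before `time1`, `dose1` on the closed interval
#' `[time1, time2]`, and `dose2` after `time2`. Continuous treatment is
#' expressed by `dose2 = dose1`; an on/off pulse by `dose2 = 0`.
#'
#' @param time1,time2 switch times in days, `time1 <= time2`.
#' @param dose1,dose2 influent HP concentrations in g/m3, non-negative.
#' @return an object of class `dose_schedule`.
#' @examples
#' dose_schedule()                          # dosing off
#' dose_schedule(dose1 = 500, dose2 = 500)  # continuous from t = 2 d
#' dose_schedule(dose1 = 500, dose2 = 0)    # 4-day pulse, t in [2, 6]
#' @export
dose_schedule <- function(time1 = 2, time2 = 6, dose1 = 0, dose2 = 0) {
  if (!is.numeric(time1) || !is.numeric(time2) || time1 > time2)
    stop("need time1 <= time2")
  if (dose1 < 0 || dose2 < 0) stop("doses must be non-negative")
  structure(list(time1 = time1, time2 = time2,
                 dose1 = dose1, dose2 = dose2),
            class = "dose_schedule")
}

#' @export
print.dose_schedule <- function(x, ...) {
  cat(sprintf("HP dosing: 0 for t < %g d; %g g/m3 on [%g, %g] d; %g g/m3 after\n",
              x$time1, x$dose1, x$time1, x$time2, x$dose2))
  invisible(x)
}

#' Influent hydrogen peroxide concentration at time t
#'
#' Evaluates the piecewise-constant dosing schedule. Vectorized over `t`.
#'
#' @param schedule a [dose_schedule()].
#' @param t time(s) in days, `t >= 0`.
#' @return influent HP concentration(s) in g/m3.
#' @examples
#' sch <- dose_schedule(time1 = 2, time2 = 6, dose1 = 500, dose2 = 0)
#' influent_hp(sch, c(1, 4, 7))  # 0, 500, 0
#' @export
influent_hp <- function(schedule, t) {
  stopifnot(inherits(schedule, "dose_schedule"), all(t >= 0))
  ifelse(t < schedule$time1, 0,
         ifelse(t <= schedule$time2, schedule$dose1, schedule$dose2))
}
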