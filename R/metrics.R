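# Derived quantities: areal biomass, viability, log reductions,
# penetration depths, consumption profiles, bulk averages.

#' Areal live and dead biomass in the film
#'
#' Midpoint integration of the particulate concentrations over depth,
#' \eqn{\int_0^{L_f} X_b\, dz}, in g per m2 of colonized surface. An
#' eradicated film carries zero areal biomass.
#'
#' @param state a state list from [biofilm_state()], or a `biofilm_sim`
#'   (optionally with `time`).
#' @param time for a `biofilm_sim`: the sampled time to use (default final).
#' @return named numeric vector `c(live = , dead = )`, g/m2.
#' @export
areal_biomass <- function(state, time = NULL) {
  if (inherits(state, "biofilm_sim")) {
    if (state$eradicated && is.null(time)) return(c(live = 0, dead = 0))
    state <- biofilm_state(state, time)
  }
  dz <- state$Lf / ncol(state$X_b)
  c(live = sum(state$X_b[1, ]) * dz, dead = sum(state$X_b[2, ]) * dz)
}

#' Log10 reduction in viable biomass
#'
#' `log10(reference / treated)`: positive when treatment reduced the
#' viable pool. A fully eradicated film (`treated = 0`) gives `Inf`.
#'
#' @param reference_live reference areal live biomass, g/m2 (> 0).
#' @param treated_live treated areal live biomass, g/m2 (>= 0).
#' @return log10 units.
#' @export
log_reduction <- function(reference_live, treated_live) {
  if (any(reference_live <= 0)) stop("reference live biomass must be positive")
  if (any(treated_live < 0)) stop("treated live biomass must be non-negative")
  ifelse(treated_live == 0, Inf, log10(reference_live / treated_live))
}

#' Planktonic log reduction under constant biocide exposure
#'
#' Closed form for freely suspended cells killed at
#' \eqn{dX/dt = -k_{dis} S_H X} with constant HP concentration:
#' \deqn{LR = k_{dis}\, S_H\, \Delta t / \ln 10.}
#' This is the benchmark against which biofilm protection is judged.
#'
#' @param S_H HP concentration, g/m3.
#' @param duration exposure time, days.
#' @param k_dis disinfection rate coefficient; default the standard 0.5.
#' @return log10 reduction.
#' @examples
#' planktonic_log_reduction(41.4, 1)  # about 9.0
#' @export
planktonic_log_reduction <- function(S_H, duration, k_dis = 0.5) {
  if (any(c(S_H, duration, k_dis) < 0)) stop("inputs must be non-negative")
  k_dis * S_H * duration / log(10)
}

#' Solute penetration depth below the film surface
#'
#' Depth (measured down from the biofilm-liquid interface) at which the
#' concentration first falls below `threshold_fraction` of its value at
#' the surface, located by linear interpolation between cell centers.
#' The surface value is the top-cell concentration. A profile that never
#' falls below the threshold penetrates fully and returns `Lf`.
#'
#' @param profile per-cell concentrations ordered from substratum (cell
#'   1) to surface (cell Nz), g/m3.
#' @param Lf film thickness, m.
#' @param threshold_fraction fraction of the surface concentration
#'   defining "depleted"; default 0.05.
#' @return penetration depth in m, in `[0, Lf]`.
#' @export
penetration_depth <- function(profile, Lf, threshold_fraction = 0.05) {
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must be in (0, 1)")
  Nz <- length(profile)
  S_surf <- profile[Nz]
  if (S_surf <= 0) return(0)
  thr <- threshold_fraction * S_surf
  zc <- ((seq_len(Nz) - 0.5) / Nz) * Lf          # depth above substratum
  depth <- Lf - zc                               # depth below surface
  # walk downward from the surface
  ord <- rev(seq_len(Nz))
  prof_d <- profile[ord]
  dep_d <- depth[ord]
  below <- which(prof_d < thr)
  if (length(below) == 0) return(Lf)
  i <- below[1]
  if (i == 1) return(dep_d[1])
  # interpolate between the last cell above threshold and the first below
  f <- (prof_d[i - 1] - thr) / (prof_d[i - 1] - prof_d[i])
  dep_d[i - 1] + f * (dep_d[i] - dep_d[i - 1])
}

#' Glucose consumption rate profile
#'
#' The volumetric glucose consumption \eqn{-R_{S:G}} in each cell
#' (non-negative); its peak marks the actively growing stratum.
#'
#' @param state a state list from [biofilm_state()] or a `biofilm_sim`.
#' @param p parameters; defaults to the simulation's own.
#' @param time for a `biofilm_sim`: sampled time (default final).
#' @return numeric vector of length Nz, g/m3/day.
#' @export
consumption_rate_profile <- function(state, p = NULL, time = NULL) {
  if (inherits(state, "biofilm_sim")) {
    if (is.null(p)) p <- state$params
    state <- biofilm_state(state, time)
  }
  if (is.null(p)) p <- biofilm_params()
  -solute_rates(pmax(state$X_b[1, ], 0), pmax(state$X_b[2, ], 0),
                pmax(state$S_b[1, ], 0), pmax(state$S_b[2, ], 0), p)$glucose
}

#' Time-averaged tank concentration
#'
#' Trapezoidal average of a tank solute over a time window, e.g. the
#' mean bulk HP concentration over the first treatment day.
#'
#' @param sim a `biofilm_sim`.
#' @param solute `"glucose"` or `"hp"`.
#' @param t_start,t_end window in days, within the simulated horizon.
#' @return mean concentration, g/m3.
#' @export
mean_bulk_concentration <- function(sim, solute = c("glucose", "hp"),
                                    t_start, t_end) {
  stopifnot(inherits(sim, "biofilm_sim"))
  solute <- match.arg(solute)
  if (t_end <= t_start) stop("empty averaging window")
  if (t_start < min(sim$times) - 1e-9 || t_end > max(sim$times) + 1e-9)
    stop("window outside the simulated horizon")
  k <- if (solute == "glucose") 1L else 2L
  tt <- sim$times
  vv <- sim$S_t[, k]
  # clip the series to the window, interpolating the end points
  sel <- tt > t_start & tt < t_end
  t_clip <- c(t_start, tt[sel], t_end)
  v_clip <- c(stats::approx(tt, vv, t_start)$y, vv[sel],
              stats::approx(tt, vv, t_end)$y)
  sum(diff(t_clip) * (utils::head(v_clip, -1) + utils::tail(v_clip, -1)) / 2) /
    (t_end - t_start)
}

#' Steady-state summary metrics of a run
#'
#' Collects the quantities used to characterize a (near-)steady film:
#' thickness, areal live/dead biomass, depth-averaged live volume
#' fraction, percent live (areal basis), solute penetration depths, the
#' final tank concentrations, and -- when a reference is supplied -- the
#' log reduction in viable areal biomass relative to it.
#'
#' @param sim a `biofilm_sim` (typically from [run_to_steady_state()]).
#' @param reference_live areal live biomass of the untreated reference,
#'   g/m2, or `NULL` to skip the log reduction.
#' @param threshold_fraction penetration-depth threshold (default 0.05).
#' @return object of class `biofilm_metrics`: a named list.
#' @export
steady_state_metrics <- function(sim, reference_live = NULL,
                                 threshold_fraction = 0.05) {
  stopifnot(inherits(sim, "biofilm_sim"))
  if (sim$eradicated) {
    out <- list(Lf_ss = 0, areal_live = 0, areal_dead = 0,
                mean_live_fraction = NA_real_, percent_live = NA_real_,
                log_reduction_ss = if (is.null(reference_live)) NA_real_ else Inf,
                penetration_glucose = 0, penetration_hp = 0,
                S_t_ss = sim$S_t[nrow(sim$S_t), ],
                eradicated = TRUE)
    return(structure(out, class = "biofilm_metrics"))
  }
  st <- biofilm_state(sim)
  ab <- areal_biomass(st)
  tot <- st$X_b[1, ] + st$X_b[2, ]
  frac <- ifelse(tot > 0, st$X_b[1, ] / tot, NA_real_)
  out <- list(
    Lf_ss = st$Lf,
    areal_live = ab[["live"]],
    areal_dead = ab[["dead"]],
    mean_live_fraction = 100 * mean(frac, na.rm = TRUE),
    percent_live = 100 * ab[["live"]] / sum(ab),
    log_reduction_ss = if (is.null(reference_live)) NA_real_ else
      log_reduction(reference_live, ab[["live"]]),
    penetration_glucose = penetration_depth(st$S_b[1, ], st$Lf,
                                            threshold_fraction),
    penetration_hp = penetration_depth(st$S_b[2, ], st$Lf,
                                       threshold_fraction),
    S_t_ss = st$S_t,
    eradicated = FALSE)
  structure(out, class = "biofilm_metrics")
}

#' @export
print.biofilm_metrics <- function(x, ...) {
  if (isTRUE(x$eradicated)) {
    cat("Biofilm eradicated: thickness below 1 um, no viable areal biomass\n")
    return(invisible(x))
  }
  cat(sprintf("Steady-state thickness:     %.1f um\n", 1e6 * x$Lf_ss))
  cat(sprintf("Areal biomass (live|dead):  %.3g | %.3g g/m2\n",
              x$areal_live, x$areal_dead))
  cat(sprintf("Mean live volume fraction:  %.1f %%\n", x$mean_live_fraction))
  if (is.finite(x$log_reduction_ss))
    cat(sprintf("Log reduction vs reference: %.3g\n", x$log_reduction_ss))
  cat(sprintf("Penetration (glucose|HP):   %.1f | %.1f um\n",
              1e6 * x$penetration_glucose, 1e6 * x$penetration_hp))
  cat(sprintf("Tank solutes (G|HP):        %.3g | %.3g g/m3\n",
              x$S_t_ss[1], x$S_t_ss[2]))
  invisible(x)
}
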