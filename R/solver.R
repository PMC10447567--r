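# Method-of-lines integration of the coupled tank + biofilm system.
#
# State vector layout (length 5 + 4*Nz):
#   y[1:2]   tank particulates [live, dead]        (g/m^3)
#   y[3:4]   tank solutes      [glucose, HP]       (g/m^3)
#   y[.. Nz] biofilm live biomass per cell         (g/m^3)
#   y[.. Nz] biofilm dead biomass per cell
#   y[.. Nz] biofilm glucose per cell
#   y[.. Nz] biofilm HP per cell
#   y[last]  biofilm thickness Lf                  (m)
#
# Rate laws see concentrations clamped at zero (transient undershoots
# from the integrator must not flip reaction signs); flow/transport
# terms act on the raw state so mass accounting stays linear.

.state_index <- function(Nz) {
  list(XtL = 1L, XtD = 2L, StG = 3L, StH = 4L,
       XL = 4L + 1:Nz, XD = 4L + Nz + 1:Nz,
       SG = 4L + 2L * Nz + 1:Nz, SH = 4L + 3L * Nz + 1:Nz,
       Lf = 5L + 4L * Nz)
}

.initial_state <- function(p) {
  Nz <- p$Nz
  c(p$X_t0, p$S_t0,
    rep(p$P_b0[1] * p$rho_L, Nz), rep(p$P_b0[2] * p$rho_D, Nz),
    rep(p$S_b0[1], Nz), rep(p$S_b0[2], Nz),
    p$Lf0)
}

# Reference right-hand side in pure R. The production integrator uses
# the compiled equivalent (src/rhs.cpp); the two are pinned against
# each other in the test suite. S_in_H is held constant within an
# integration segment; dosing discontinuities are handled by splitting
# the horizon at time1/time2 so the integrator never steps across a
# jump.
.biofilm_rhs_r <- function(t, y, p, S_in_H) {
  Nz <- p$Nz
  i0 <- 4L
  Lf <- max(y[i0 + 4L * Nz + 1L], p$Lf_floor)
  dz <- Lf / Nz

  XL <- pmax(y[i0 + 1:Nz], 0)
  XD <- pmax(y[i0 + Nz + 1:Nz], 0)
  SG <- pmax(y[i0 + 2L * Nz + 1:Nz], 0)
  SH <- pmax(y[i0 + 3L * Nz + 1:Nz], 0)

  # local kinetics in the film
  mu <- p$mu_max * SG / (p$K_M + SG)
  kill <- p$k_dis * SH * XL
  RXL <- mu * XL - kill
  RXD <- kill
  RSG <- -mu * XL / p$Y_GL
  RSH <- -(p$k_B_L * XL + p$k_B_D * XD) * SH

  # growth velocity at faces (midpoint rule on the volumetric source)
  Ptot <- XL / p$rho_L + XD / p$rho_D
  src <- ifelse(Ptot > 0, (RXL / p$rho_L + RXD / p$rho_D) / Ptot, 0)
  v <- c(0, cumsum(src) * dz)
  v_det <- p$K_det * Lf^2
  dLf <- v[Nz + 1L] - v_det
  if (y[i0 + 4L * Nz + 1L] <= p$Lf_floor && dLf < 0) dLf <- 0

  # particulate transport: upwind flux at velocity relative to the grid
  w <- v - (0:Nz) / Nz * dLf
  wp <- pmax(w, 0)
  wm <- pmin(w, 0)
  fL <- numeric(Nz + 1L)
  fD <- numeric(Nz + 1L)
  fL[2:Nz] <- wp[2:Nz] * XL[1:(Nz - 1L)] + wm[2:Nz] * XL[2:Nz]
  fD[2:Nz] <- wp[2:Nz] * XD[1:(Nz - 1L)] + wm[2:Nz] * XD[2:Nz]
  fL[Nz + 1L] <- wp[Nz + 1L] * XL[Nz]
  fD[Nz + 1L] <- wp[Nz + 1L] * XD[Nz]
  dil <- dLf / Lf
  dXL <- -diff(fL) / dz - XL * dil + RXL
  dXD <- -diff(fD) / dz - XD * dil + RXD

  # solute diffusion with Robin surface closure, plus the grid-motion
  # advection that the moving coordinate induces on the solute fields
  StG <- y[3L]
  StH <- y[4L]
  dSG <- numeric(Nz)
  dSH <- numeric(Nz)
  J_dif <- numeric(2)
  half <- dz / 2
  S_top <- c(StG, StH)
  D_b <- c(p$D_b_G, p$D_b_H)
  D_aq <- c(p$D_aq_G, p$D_aq_H)
  zc <- ((1:Nz) - 0.5) / Nz
  for (k in 1:2) {
    S <- if (k == 1L) SG else SH
    a <- D_b[k] / half
    b <- D_aq[k] / p$L_L
    S_surf <- (a * S[Nz] + b * S_top[k]) / (a + b)
    g <- numeric(Nz + 1L)
    g[2:Nz] <- D_b[k] * diff(S) / dz
    g[Nz + 1L] <- a * (S_surf - S[Nz])
    diffterm <- diff(g) / dz
    # upwinded zeta*dLf/dt * dS/dz (zero-gradient at the substratum)
    if (dLf > 0) {
      grad <- c(0, diff(S)) / dz
    } else {
      grad <- c(diff(S) / dz, (S_surf - S[Nz]) / half)
    }
    adv <- zc * dLf * grad
    if (k == 1L) dSG <- diffterm + adv + RSG else dSH <- diffterm + adv + RSH
    J_dif[k] <- -g[Nz + 1L]
  }

  # tank balances (CSTR with detachment and diffusive exchange)
  QV <- p$Q / p$V
  AV <- p$A / p$V
  XtLc <- max(y[1L], 0)
  XtDc <- max(y[2L], 0)
  StGc <- max(StG, 0)
  StHc <- max(StH, 0)
  mu_t <- p$mu_max * StGc / (p$K_M + StGc)
  kill_t <- p$k_dis * StHc * XtLc
  dXtL <- -QV * y[1L] + v_det * XL[Nz] * AV + mu_t * XtLc - kill_t
  dXtD <- -QV * y[2L] + v_det * XD[Nz] * AV + kill_t
  dStG <- QV * (p$S_in_G - StG) + J_dif[1L] * AV - mu_t * XtLc / p$Y_GL
  dStH <- QV * (S_in_H - StH) + J_dif[2L] * AV -
    (p$k_B_L * XtLc + p$k_B_D * XtDc) * StHc

  dy <- c(dXtL, dXtD, dStG, dStH, dXL, dXD, dSG, dSH, dLf)
  if (any(!is.finite(dy))) {
    idx <- .state_index(Nz)
    bad <- which(!is.finite(dy))[1L]
    field <- names(idx)[vapply(idx, function(i) bad %in% i, logical(1))][1L]
    stop("non-finite time derivative in state field '", field,
         "' at t = ", signif(t, 6))
  }
  list(dy)
}

# parameter vector for the compiled RHS; order must match src/rhs.cpp
.pack_params <- function(p) {
  c(p$Nz, p$mu_max, p$K_M, p$Q, p$V, p$A, p$k_dis, p$Y_GL, p$S_in_G,
    p$k_B_L, p$k_B_D, p$rho_L, p$rho_D, p$D_b_G, p$D_b_H, p$D_aq_G,
    p$D_aq_H, p$L_L, p$K_det, p$Lf_floor)
}

# fast RHS for deSolve: compiled core plus a finite-ness guard
.biofilm_rhs <- function(t, y, parms, S_in_H) {
  dy <- biofilm_rhs_core(t, y, parms, S_in_H)
  if (any(!is.finite(dy))) {
    Nz <- (length(y) - 5L) %/% 4L
    idx <- .state_index(Nz)
    bad <- which(!is.finite(dy))[1L]
    field <- names(idx)[vapply(idx, function(i) bad %in% i, logical(1))][1L]
    stop("non-finite time derivative in state field '", field,
         "' at t = ", signif(t, 6))
  }
  list(dy)
}

#' Time derivative of the full system state
#'
#' Assembles the right-hand side of the coupled model at one instant:
#' tank balances (flow, detachment influx, diffusive exchange, local
#' kinetics), biofilm particulate advection and solute
#' diffusion-reaction on the moving grid, and the thickness equation
#' \eqn{dL_f/dt = v(L_f) - v_{det}}.
#'
#' This is the reference assembly in pure R, useful for inspecting
#' fixed points and for testing; [simulate_biofilm()] integrates a
#' compiled equivalent, and the two are pinned against each other in
#' the test suite.
#'
#' @param state list with elements `X_t` (length 2), `S_t` (length 2),
#'   `X_b` (2 x Nz), `S_b` (2 x Nz), `Lf` (scalar, m) and optionally `t`.
#' @param p a [biofilm_params()] object.
#' @param schedule a [dose_schedule()].
#' @param t time in days; defaults to `state$t` or 0.
#' @return list of derivatives with the same shapes: `dX_t`, `dS_t`,
#'   `dX_b`, `dS_b`, `dLf`.
#' @export
biofilm_derivatives <- function(state, p = biofilm_params(),
                                schedule = dose_schedule(), t = NULL) {
  if (is.null(t)) t <- if (!is.null(state$t)) state$t else 0
  Nz <- p$Nz
  stopifnot(ncol(state$X_b) == Nz, ncol(state$S_b) == Nz)
  y <- c(state$X_t, state$S_t,
         state$X_b[1, ], state$X_b[2, ],
         state$S_b[1, ], state$S_b[2, ],
         state$Lf)
  dy <- .biofilm_rhs_r(t, y, p, influent_hp(schedule, t))[[1]]
  idx <- .state_index(Nz)
  list(dX_t = dy[1:2], dS_t = dy[3:4],
       dX_b = rbind(dy[idx$XL], dy[idx$XD]),
       dS_b = rbind(dy[idx$SG], dy[idx$SH]),
       dLf = dy[idx$Lf])
}

#' Simulate the biofilm-tank system through time
#'
#' Integrates the full coupled stiff system with `deSolve`'s `lsodar`
#' (adaptive, automatic stiff/non-stiff switching) from the standard
#' initial condition: biofilm particulates from the initial volume
#' fractions (`X_b = P_b0 * rho`), solutes in the film starting at their
#' configured initial values. The horizon is split at the dosing switch
#' times so the influent HP discontinuities are never stepped across. A
#' root function on the film thickness terminates the run as soon as
#' `Lf` falls below the eradication threshold (1 um by default); this is
#' reported as a normal outcome, not an error.
#'
#' @param p a [biofilm_params()] object.
#' @param schedule a [dose_schedule()].
#' @param t_final horizon in days; defaults to `p$t_final`.
#' @param sample_times output times; defaults to a dense grid (about 400
#'   samples plus quarter-day resolution over the first 10 days, so the
#'   early thickness dynamics and the dosing onset are resolved).
#' @param t_start start time in days (default 0); together with `init`
#'   this continues a previous run.
#' @param init optional initial state (a list as returned by
#'   [biofilm_state()]); default is the standard initial condition.
#' @return an object of class `biofilm_sim` with elements `times`, `Lf`,
#'   `X_t`, `S_t` (matrices, one row per sample), `X_b`, `S_b` (arrays
#'   `n x 2 x Nz`), `eradicated`, `t_eradicated`, `params`, `schedule`
#'   and solver `diagnostics`.
#' @examples
#' \donttest{
#' sim <- simulate_biofilm(biofilm_params(), dose_schedule(), t_final = 5)
#' tail(sim$Lf, 1) * 1e6  # thickness in microns
#' }
#' @export
simulate_biofilm <- function(p = biofilm_params(), schedule = dose_schedule(),
                             t_final = NULL, sample_times = NULL,
                             t_start = 0, init = NULL) {
  stopifnot(inherits(p, "biofilm_params"), inherits(schedule, "dose_schedule"))
  if (is.null(t_final)) t_final <- p$t_final
  if (t_final <= t_start) stop("t_final must exceed t_start")
  if (is.null(sample_times)) {
    sample_times <- sort(unique(c(
      seq(t_start, t_final, length.out = 401),
      seq(t_start, min(t_start + 10, t_final), by = 0.25),
      schedule$time1, schedule$time2)))
    sample_times <- sample_times[sample_times <= t_final &
                                   sample_times >= t_start]
  } else {
    sample_times <- sort(unique(c(t_start, sample_times)))
    if (any(sample_times < t_start) || max(sample_times) > t_final)
      stop("sample_times must lie in [t_start, t_final]")
    if (max(sample_times) < t_final)
      sample_times <- c(sample_times, t_final)
  }

  Nz <- p$Nz
  idx <- .state_index(Nz)
  breaks <- sort(unique(c(t_start, schedule$time1, schedule$time2, t_final)))
  breaks <- breaks[breaks >= t_start & breaks <= t_final]
  rootfun <- function(t, y, parms, ...) y[idx$Lf] - p$Lf_eradicate

  y <- if (is.null(init)) .initial_state(p) else {
    stopifnot(ncol(init$X_b) == Nz, ncol(init$S_b) == Nz)
    c(init$X_t, init$S_t, init$X_b[1, ], init$X_b[2, ],
      init$S_b[1, ], init$S_b[2, ], init$Lf)
  }
  # absolute tolerance per component: concentrations are O(1e2..1e4)
  # g/m^3, the thickness is O(1e-4) m, so a single scalar would either
  # over-resolve the solutes or under-resolve Lf
  atv <- rep(p$atol, length(y))
  atv[idx$Lf] <- p$atol_Lf
  packed <- .pack_params(p)
  rows <- list()
  eradicated <- FALSE
  t_erad <- NA_real_
  nsteps <- 0L
  for (s in seq_len(length(breaks) - 1L)) {
    a <- breaks[s]
    b <- breaks[s + 1L]
    if (b <= a) next
    tt <- sort(unique(c(a, sample_times[sample_times > a & sample_times < b], b)))
    S_in_H <- influent_hp(schedule, (a + b) / 2)
    out <- suppressWarnings(
      deSolve::lsodar(y = y, times = tt, func = .biofilm_rhs,
                      parms = packed, S_in_H = S_in_H,
                      rtol = p$rtol, atol = atv,
                      rootfunc = rootfun, maxsteps = 20000))
    ist <- attr(out, "istate")
    if (!is.null(ist) && length(ist) >= 3 && is.finite(ist[3]))
      nsteps <- nsteps + ist[3]
    t_end <- out[nrow(out), 1L]
    hit_root <- function(o) {
      tr <- attr(o, "troot")
      !is.null(tr) && length(tr) > 0 && is.finite(tr[1])
    }
    root <- hit_root(out)
    if (t_end < b - 1e-9 && !root) {
      # multistep breakdown: in a near-collapsed film the solute
      # diffusion rate D/dz^2 diverges and lsodar can stall; the
      # L-stable implicit Runge-Kutta finishes the leg
      tt2 <- c(t_end, tt[tt > t_end + 1e-12])
      out2 <- suppressWarnings(
        deSolve::radau(y = out[nrow(out), -1L], times = tt2,
                       func = .biofilm_rhs, parms = packed, S_in_H = S_in_H,
                       rtol = p$rtol, atol = atv,
                       rootfunc = rootfun, maxsteps = 200000))
      root <- hit_root(out2)
      t_end <- out2[nrow(out2), 1L]
      if (t_end < b - 1e-9 && !root)
        stop("integration stopped early at t = ", signif(t_end, 6),
             " d without reaching an eradication root (solver failure)")
      out <- rbind(out, out2[-1L, , drop = FALSE])
    }
    keep <- if (s == 1L) seq_len(nrow(out)) else -1L
    rows[[s]] <- out[keep, , drop = FALSE]
    y <- out[nrow(out), -1L]
    if (root) {
      # terminal root: film thickness fell below the eradication level
      eradicated <- TRUE
      t_erad <- t_end
      break
    }
  }
  m <- do.call(rbind, rows)
  dimnames(m) <- NULL
  # a solver leg that stops early re-reports its end state; keep each
  # sample time once
  m <- m[c(TRUE, diff(m[, 1L]) > 1e-9), , drop = FALSE]
  times <- m[, 1L]
  n <- length(times)
  X_b <- array(0, dim = c(n, 2, Nz))
  S_b <- array(0, dim = c(n, 2, Nz))
  X_b[, 1, ] <- m[, 1L + idx$XL, drop = FALSE]
  X_b[, 2, ] <- m[, 1L + idx$XD, drop = FALSE]
  S_b[, 1, ] <- m[, 1L + idx$SG, drop = FALSE]
  S_b[, 2, ] <- m[, 1L + idx$SH, drop = FALSE]
  structure(list(
    times = times,
    Lf = m[, 1L + idx$Lf],
    X_t = m[, 1L + 1:2, drop = FALSE],
    S_t = m[, 1L + 3:4, drop = FALSE],
    X_b = X_b,
    S_b = S_b,
    eradicated = eradicated,
    t_eradicated = t_erad,
    params = p,
    schedule = schedule,
    t_final = t_final,
    diagnostics = list(n_steps = nsteps, n_samples = n,
                       rtol = p$rtol, atol = p$atol)
  ), class = "biofilm_sim")
}

#' @export
print.biofilm_sim <- function(x, ...) {
  cat(sprintf("Biofilm simulation: %d samples over %.4g d (Nz = %d)\n",
              length(x$times), max(x$times), x$params$Nz))
  cat(sprintf("  dosing: %g g/m3 on [%g, %g] d, then %g g/m3\n",
              x$schedule$dose1, x$schedule$time1, x$schedule$time2,
              x$schedule$dose2))
  if (x$eradicated) {
    cat(sprintf("  biofilm ERADICATED at t = %.4g d\n", x$t_eradicated))
  } else {
    cat(sprintf("  final thickness: %.4g um\n", 1e6 * tail_1(x$Lf)))
  }
  invisible(x)
}

tail_1 <- function(v) v[length(v)]

#' Extract the system state at one sampled time
#'
#' @param sim a `biofilm_sim` object.
#' @param time requested time in days; the nearest sampled time is used
#'   (error if it differs by more than `tol`). Default: final sample.
#' @param tol matching tolerance in days.
#' @return list with `X_t`, `S_t`, `X_b` (2 x Nz), `S_b` (2 x Nz), `Lf`, `t`.
#' @export
biofilm_state <- function(sim, time = NULL, tol = 1e-6) {
  stopifnot(inherits(sim, "biofilm_sim"))
  i <- if (is.null(time)) length(sim$times) else which.min(abs(sim$times - time))
  if (!is.null(time) && abs(sim$times[i] - time) > tol)
    stop("no sample within ", tol, " d of t = ", time,
         " (nearest: ", sim$times[i], ")")
  list(X_t = sim$X_t[i, ], S_t = sim$S_t[i, ],
       X_b = matrix(sim$X_b[i, , ], 2), S_b = matrix(sim$S_b[i, , ], 2),
       Lf = sim$Lf[i], t = sim$times[i])
}

#' Tidy time series of tank-level quantities
#'
#' @param x a `biofilm_sim`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with columns `time` (d), `Lf_um`, tank
#'   concentrations, and areal live/dead biomass in the film (g/m2).
#' @export
as.data.frame.biofilm_sim <- function(x, row.names = NULL, optional = FALSE, ...) {
  n <- length(x$times)
  Nz <- x$params$Nz
  dz <- x$Lf / Nz
  areal_live <- rowSums(matrix(x$X_b[, 1, ], nrow = n)) * dz
  areal_dead <- rowSums(matrix(x$X_b[, 2, ], nrow = n)) * dz
  data.frame(time = x$times,
             Lf_um = 1e6 * x$Lf,
             X_t_live = x$X_t[, 1], X_t_dead = x$X_t[, 2],
             S_t_glucose = x$S_t[, 1], S_t_hp = x$S_t[, 2],
             areal_live = areal_live, areal_dead = areal_dead)
}

#' Depth profile of the film at one sampled time
#'
#' @param sim a `biofilm_sim`.
#' @param time requested time (nearest sample); default final.
#' @return data.frame with depth coordinate `z_um` (0 = substratum),
#'   particulate concentrations, volume fractions, solute concentrations
#'   and the local glucose consumption rate.
#' @export
biofilm_profile <- function(sim, time = NULL) {
  st <- biofilm_state(sim, time, tol = Inf)
  p <- sim$params
  g <- biofilm_grid(p$Nz)
  cons <- -solute_rates(st$X_b[1, ], st$X_b[2, ],
                        pmax(st$S_b[1, ], 0), pmax(st$S_b[2, ], 0),
                        p)$glucose
  data.frame(
    z_um = 1e6 * g$zeta_centers * st$Lf,
    zeta = g$zeta_centers,
    X_b_live = st$X_b[1, ], X_b_dead = st$X_b[2, ],
    P_live = st$X_b[1, ] / p$rho_L, P_dead = st$X_b[2, ] / p$rho_D,
    S_b_glucose = st$S_b[1, ], S_b_hp = st$S_b[2, ],
    glucose_consumption = cons)
}

.stitch_sims <- function(a, b) {
  # append continuation run b (starting at a's final time) to a
  keep <- -1L  # b's first sample duplicates a's last
  out <- a
  out$times <- c(a$times, b$times[keep])
  out$Lf <- c(a$Lf, b$Lf[keep])
  out$X_t <- rbind(a$X_t, b$X_t[keep, , drop = FALSE])
  out$S_t <- rbind(a$S_t, b$S_t[keep, , drop = FALSE])
  n <- length(out$times)
  Nz <- dim(a$X_b)[3]
  for (f in c("X_b", "S_b")) {
    arr <- array(0, dim = c(n, 2, Nz))
    arr[seq_along(a$times), , ] <- a[[f]]
    arr[-seq_along(a$times), , ] <- b[[f]][keep, , , drop = FALSE]
    out[[f]] <- arr
  }
  out$eradicated <- b$eradicated
  out$t_eradicated <- b$t_eradicated
  out$t_final <- b$t_final
  out$diagnostics$n_steps <- a$diagnostics$n_steps + b$diagnostics$n_steps
  out$diagnostics$n_samples <- n
  out
}

#' Run a scenario until it reaches steady state
#'
#' Integrates over `t_init` days and tests whether both the film
#' thickness and the areal live biomass changed by less than `rel_tol`
#' (relative) over the final 10 percent of the horizon. If not, the
#' horizon is doubled and integration continues from the state already
#' reached, up to `t_cap` (slow dynamics near the film base can take
#' hundreds of days to settle). Eradication terminates the search.
#'
#' @param p a [biofilm_params()] object.
#' @param schedule a [dose_schedule()].
#' @param t_init initial horizon, days.
#' @param t_cap maximum horizon, days.
#' @param rel_tol steady-state criterion on the relative change.
#' @return the full stitched `biofilm_sim`, with extra fields `steady`
#'   (logical) and `t_horizon`.
#' @export
run_to_steady_state <- function(p = biofilm_params(),
                                schedule = dose_schedule(),
                                t_init = 100, t_cap = 2000,
                                rel_tol = 1e-3) {
  sim <- simulate_biofilm(p, schedule, t_final = t_init)
  tf <- t_init
  repeat {
    if (sim$eradicated) {
      sim$steady <- TRUE
      sim$t_horizon <- tf
      return(sim)
    }
    win <- sim$times >= 0.9 * max(sim$times)
    lf_w <- sim$Lf[win]
    XbL <- matrix(sim$X_b[, 1, ], nrow = length(sim$times))
    al_w <- rowSums(XbL[win, , drop = FALSE]) * lf_w / p$Nz
    rel <- function(v) (max(v) - min(v)) / max(max(abs(v)), 1e-12)
    steady <- rel(lf_w) < rel_tol && rel(al_w) < rel_tol
    if (steady || tf >= t_cap) {
      sim$steady <- steady
      sim$t_horizon <- tf
      return(sim)
    }
    new_tf <- min(2 * tf, t_cap)
    ext <- simulate_biofilm(p, schedule, t_final = new_tf,
                            t_start = tf, init = biofilm_state(sim))
    sim <- .stitch_sims(sim, ext)
    tf <- new_tf
  }
}
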