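# Spatial discretization on the moving film.
#
# The film [0, Lf(t)] is mapped to the fixed normalized coordinate
# zeta = z/Lf with Nz uniform finite-volume cells, so the ODE system has
# a fixed size while the physical domain moves. Chain-rule terms (1/Lf
# per spatial derivative) and an upwinded grid-motion flux zeta*dLf/dt
# appear in the transport operators below.

#' Uniform normalized grid across the biofilm
#'
#' @param Nz number of cells, at least 2.
#' @return object of class `biofilm_grid` with `Nz`, `zeta_centers`
#'   (cell centers \eqn{(i - 1/2)/N_z}) and `zeta_faces` (`Nz + 1` face
#'   coordinates from 0 to 1). Physical depth is `z = zeta * Lf`.
#' @export
biofilm_grid <- function(Nz) {
  Nz <- as.integer(Nz)
  if (Nz < 2) stop("Nz must be at least 2")
  structure(list(Nz = Nz,
                 zeta_centers = (seq_len(Nz) - 0.5) / Nz,
                 zeta_faces = (0:Nz) / Nz),
            class = "biofilm_grid")
}

#' Growth-induced advective velocity at cell faces
#'
#' Volumetric biomass production below depth z pushes particulates
#' upward with velocity
#' \deqn{v(z) = \int_0^z \frac{1}{P_{tot}} \sum_j \frac{R_{X:j}}{\rho_j}\, dz',}
#' where \eqn{P_{tot} = \sum_j X_{b:j}/\rho_j} is the total particulate
#' volume fraction. Discretized by the midpoint rule cell by cell, so
#' the velocity is defined at the `Nz + 1` faces with `v[1] = 0` at the
#' substratum.
#'
#' @param X_b 2 x Nz matrix of particulate concentrations (rows
#'   `[live, dead]`), g/m3.
#' @param S_b 2 x Nz matrix of solute concentrations (rows
#'   `[glucose, HP]`), g/m3.
#' @param Lf film thickness, m.
#' @param p a [biofilm_params()] object.
#' @param grid a [biofilm_grid()]; defaults to `biofilm_grid(ncol(X_b))`.
#' @return numeric vector of `Nz + 1` face velocities, m/day.
#' @export
growth_velocity <- function(X_b, S_b, Lf, p = biofilm_params(), grid = NULL) {
  if (is.null(grid)) grid <- biofilm_grid(ncol(X_b))
  Ptot <- X_b[1, ] / p$rho_L + X_b[2, ] / p$rho_D
  if (any(Ptot <= 0))
    stop("degenerate state: zero particulate volume fraction in a cell")
  r <- particulate_rates(X_b[1, ], X_b[2, ], pmax(S_b[1, ], 0),
                         pmax(S_b[2, ], 0), p)
  integrand <- (r$live / p$rho_L + r$dead / p$rho_D) / Ptot  # 1/day
  c(0, cumsum(integrand) * (Lf / grid$Nz))
}

#' Particulate transport term on the moving grid
#'
#' Conservative first-order upwind discretization of
#' \eqn{-\partial(v X)/\partial z} expressed in the moving normalized
#' coordinate. The face flux uses the velocity relative to the grid,
#' \eqn{w = v - \zeta\, dL_f/dt}, with the donor cell chosen by the sign
#' of `w`; the chain rule additionally contributes a uniform dilation
#' term \eqn{-X\,(dL_f/dt)/L_f}. The substratum face carries zero flux;
#' at the surface the relative velocity equals the detachment velocity,
#' so material leaves by outflow upwinded from the top cell.
#'
#' @param X_b 2 x Nz particulate concentration matrix, g/m3.
#' @param v_faces `Nz + 1` face velocities from [growth_velocity()], m/day.
#' @param dLf_dt rate of change of film thickness, m/day.
#' @param Lf film thickness, m.
#' @param grid a [biofilm_grid()].
#' @return 2 x Nz matrix of transport contributions, g/m3/day.
#' @export
particulate_advection <- function(X_b, v_faces, dLf_dt, Lf, grid) {
  Nz <- grid$Nz
  dz <- Lf / Nz
  w <- v_faces - grid$zeta_faces * dLf_dt
  wp <- pmax(w, 0)
  wm <- pmin(w, 0)
  out <- matrix(0, 2, Nz)
  for (j in 1:2) {
    X <- X_b[j, ]
    f <- numeric(Nz + 1)                      # flux through each face
    f[2:Nz] <- wp[2:Nz] * X[1:(Nz - 1)] + wm[2:Nz] * X[2:Nz]
    f[Nz + 1] <- wp[Nz + 1] * X[Nz]           # outflow from the top cell
    out[j, ] <- -diff(f) / dz - X * dLf_dt / Lf
  }
  out
}

#' Solute diffusion-reaction transport with boundary-layer flux matching
#'
#' Central second difference of \eqn{D_b \partial^2 S/\partial z^2} with
#' a zero-gradient condition at the substratum and a Robin closure at
#' the surface: the in-film flux toward the top cell equals the flux
#' through a stagnant boundary layer of thickness `L_L`,
#' \eqn{D_b (S_{surf} - S_{top})/(\Delta z/2) = D_{aq} (S_t - S_{surf})/L_L},
#' solved for the surface concentration \eqn{S_{surf}}. Also returns the
#' film-to-tank flux `J_dif` (positive when solute leaves the film) used
#' in the tank balance.
#'
#' @param S_b 2 x Nz solute concentration matrix (rows `[glucose, HP]`), g/m3.
#' @param S_t length-2 tank solute concentrations `[glucose, HP]`, g/m3.
#' @param Lf film thickness, m (> 0).
#' @param p a [biofilm_params()] object.
#' @param grid a [biofilm_grid()].
#' @return list with `term` (2 x Nz diffusion contributions, g/m3/day),
#'   `J_dif` (length-2 film-to-tank flux, g/m2/day) and `S_surface`
#'   (length-2 interface concentrations, g/m3).
#' @export
solute_diffusion <- function(S_b, S_t, Lf, p = biofilm_params(), grid = NULL) {
  if (Lf <= 0) stop("film thickness must be positive")
  if (is.null(grid)) grid <- biofilm_grid(ncol(S_b))
  Nz <- grid$Nz
  dz <- Lf / Nz
  D_b <- c(p$D_b_G, p$D_b_H)
  D_aq <- c(p$D_aq_G, p$D_aq_H)
  term <- matrix(0, 2, Nz)
  J_dif <- numeric(2)
  S_surface <- numeric(2)
  for (k in 1:2) {
    S <- S_b[k, ]
    a <- D_b[k] / (dz / 2)      # in-film half-cell conductance
    b <- D_aq[k] / p$L_L        # boundary-layer conductance
    S_surf <- (a * S[Nz] + b * S_t[k]) / (a + b)
    g <- numeric(Nz + 1)        # D * dS/dz at each face (upward gradient)
    if (Nz > 1) g[2:Nz] <- D_b[k] * diff(S) / dz
    g[Nz + 1] <- a * (S_surf - S[Nz])   # influx through the surface
    term[k, ] <- diff(g) / dz
    J_dif[k] <- -g[Nz + 1]              # positive out of the film
    S_surface[k] <- S_surf
  }
  names(J_dif) <- names(S_surface) <- c("glucose", "hp")
  list(term = term, J_dif = J_dif, S_surface = S_surface)
}
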