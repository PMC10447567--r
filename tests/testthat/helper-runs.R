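# Shared, lazily computed simulation runs. The expensive scenario runs
# are reused across test files instead of being recomputed.

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

# Untreated base case run to steady state (Table-standard parameters).
case_A_sim <- function() cached_run("case_A", {
  run_to_steady_state(biofilm_params(), dose_schedule(), t_init = 100)
})

# Continuous 500 g/m3 dosing, finely sampled over the onset window so
# one-day windows starting at the dose onset are well resolved.
case_B_sim <- function() cached_run("case_B", {
  st <- sort(unique(c(seq(0, 10, by = 0.01), seq(10, 100, by = 0.5))))
  simulate_biofilm(biofilm_params(), dose_schedule(dose1 = 500, dose2 = 500),
                   t_final = 100, sample_times = st)
})

# Long-horizon continuous dosing run; the dead fraction near the film
# base settles on a hundreds-of-days timescale.
case_B_long_sim <- function() cached_run("case_B_long", {
  simulate_biofilm(biofilm_params(), dose_schedule(dose1 = 500, dose2 = 500),
                   t_final = 2000)
})

# Mean viable (live) biomass concentration across the film, g/m^3.
mean_live_concentration <- function(sim, time = NULL) {
  st <- biofilm_state(sim, time)
  mean(st$X_b[1, ])
}

# Maximum relative error of the discrete steady reaction-diffusion
# profile against the analytic cosh solution, for frozen biomass
# consuming HP at first order (rate kr) behind the boundary layer.
cosh_profile_error <- function(Nz, kr = 5000, Lf = 150e-6,
                               S_tank = 500, p = biofilm_params()) {
  lambda <- sqrt(p$D_b_H / kr)
  b <- p$D_aq_H / p$L_L
  Cc <- b * S_tank /
    (p$D_b_H * sinh(Lf / lambda) / lambda + b * cosh(Lf / lambda))
  g <- biofilm_grid(Nz)
  S_t <- c(0, S_tank)
  base <- solute_diffusion(rbind(rep(0, Nz), rep(0, Nz)), S_t, Lf, p, g)$term[2, ]
  M <- matrix(0, Nz, Nz)
  for (i in seq_len(Nz)) {
    e <- rep(0, Nz)
    e[i] <- 1
    M[, i] <- solute_diffusion(rbind(rep(0, Nz), e), S_t, Lf, p, g)$term[2, ] - base
  }
  S_num <- solve(M - kr * diag(Nz), -base)
  S_exact <- Cc * cosh(g$zeta_centers * Lf / lambda)
  max(abs(S_num - S_exact) / S_exact)
}
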