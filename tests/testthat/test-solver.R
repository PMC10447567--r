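p0 <- biofilm_params()

test_that("a motionless equilibrium state has zero time derivative", {
  # all kinetics and detachment switched off, solutes equilibrated with
  # the tank, influent equal to the tank concentration: a fixed point
  p <- biofilm_params(mu_max = 0, k_dis = 0, k_B_L = 0, k_B_D = 0,
                      K_det = 0, S_in_G = 100)
  Nz <- p$Nz
  st <- list(X_t = c(0, 0), S_t = c(100, 0),
             X_b = rbind(rep(2e4, Nz), rep(0, Nz)),
             S_b = rbind(rep(100, Nz), rep(0, Nz)),
             Lf = 80e-6)
  d <- biofilm_derivatives(st, p, dose_schedule(), t = 0)
  expect_equal(d$dX_t, c(0, 0))
  expect_equal(d$dS_t, c(0, 0), tolerance = 1e-12)
  expect_equal(d$dX_b, matrix(0, 2, Nz))
  expect_equal(max(abs(d$dS_b)), 0, tolerance = 1e-9)
  expect_equal(d$dLf, 0)
})

test_that("detachment flux feeds the tank at v_det * X_top", {
  # film at 150 um releasing uniform live biomass of 2e4 g/m3:
  # J_det = K_det * Lf^2 * X_top = 4.5 g/m2/d, scaled by A/V in the tank
  p <- biofilm_params()
  Nz <- p$Nz
  st <- list(X_t = c(0, 0), S_t = c(0, 0),
             X_b = rbind(rep(2e4, Nz), rep(0, Nz)),
             S_b = rbind(rep(0, Nz), rep(0, Nz)),
             Lf = 150e-6)
  d <- biofilm_derivatives(st, p, dose_schedule(), t = 0)
  expect_equal(d$dX_t[1], 4.5 * p$A / p$V)
  expect_equal(d$dX_t[2], 0)
  expect_equal(d$dLf, -2.25e-4)  # no growth, pure detachment
})

test_that("suspended cells wash out when the film is uncoupled (A = 0)", {
  # dilution rate Q/V = 10/d exceeds mu_max = 9.6/d, so a chemostat
  # alone cannot retain biomass
  p <- biofilm_params(A = 0)
  sim <- simulate_biofilm(p, dose_schedule(), t_final = 20)
  xl <- sim$X_t[, 1]
  expect_lt(xl[length(xl)], 0.02 * xl[1])
  late <- sim$X_t[sim$times > 2, 1]
  expect_true(all(diff(late) <= 1e-9))
})

test_that("total particulate volume fraction is conserved at 0.08", {
  sim <- case_A_sim()
  p <- sim$params
  for (tm in c(1, 10, max(sim$times))) {
    st <- biofilm_state(sim, tm, tol = Inf)
    ptot <- st$X_b[1, ] / p$rho_L + st$X_b[2, ] / p$rho_D
    expect_lt(max(abs(ptot - 0.08) / 0.08), 1e-3)
  }
  # also under heavy dosing, where dead cells accumulate
  simB <- case_B_long_sim()
  st <- biofilm_state(simB)
  ptot <- st$X_b[1, ] / p$rho_L + st$X_b[2, ] / p$rho_D
  expect_lt(max(abs(ptot - 0.08) / 0.08), 1e-3)
})

test_that("steady state balances growth velocity against detachment", {
  sim <- case_A_sim()
  expect_true(sim$steady)
  st <- biofilm_state(sim)
  p <- sim$params
  v <- growth_velocity(st$X_b, st$S_b, st$Lf, p, biofilm_grid(p$Nz))
  v_det <- detachment_velocity(st$Lf, p)
  expect_lt(abs(v[p$Nz + 1] - v_det) / v_det, 1e-3)
})

test_that("glucose mass balance closes at steady state", {
  sim <- case_A_sim()
  p <- sim$params
  st <- biofilm_state(sim)
  J <- solute_diffusion(st$S_b, st$S_t, st$Lf, p, biofilm_grid(p$Nz))$J_dif
  R_tank <- solute_rates(max(st$X_t[1], 0), max(st$X_t[2], 0),
                         max(st$S_t[1], 0), max(st$S_t[2], 0), p)$glucose
  residual <- p$Q * (p$S_in_G - st$S_t[1]) + p$A * J[["glucose"]] +
    p$V * R_tank
  expect_lt(abs(residual) / (p$Q * p$S_in_G), 0.005)
})

test_that("HP has no feedback on growth when disinfection is off", {
  # with k_dis = 0 the live-biomass and thickness dynamics decouple
  # from the biocide entirely
  sch <- dose_schedule(dose1 = 500, dose2 = 500)
  tt <- seq(0, 30, by = 0.25)
  s_ref <- simulate_biofilm(biofilm_params(), dose_schedule(),
                            t_final = 30, sample_times = tt)
  s_kd0 <- simulate_biofilm(biofilm_params(k_dis = 0), sch,
                            t_final = 30, sample_times = tt)
  expect_equal(s_kd0$Lf, s_ref$Lf, tolerance = 1e-4)
  expect_gt(max(s_kd0$S_t[, 2]), 0)  # biocide is present, just harmless
})

test_that("compiled and reference right-hand sides agree", {
  set.seed(123)
  for (i in 1:10) {
    Nz <- sample(c(5L, 23L, 50L), 1)
    p <- biofilm_params(Nz = Nz)
    y <- c(runif(2, 0, 30), runif(2, 0, 300),
           runif(Nz, 0, 3e4), runif(Nz, 0, 3e4),
           runif(Nz, 0, 150), runif(Nz, 0, 800),
           runif(1, 2e-6, 3e-4))
    # include a few transient negative undershoots, as the integrator
    # can produce them
    y[sample(5:(4 + 4 * Nz), 3)] <- -runif(3, 0, 1e-4)
    S_in_H <- runif(1, 0, 1000)
    d_ref <- biofilmHP:::.biofilm_rhs_r(1, y, p, S_in_H)[[1]]
    d_cpp <- biofilmHP:::.biofilm_rhs(1, y, biofilmHP:::.pack_params(p),
                                      S_in_H)[[1]]
    expect_equal(d_cpp, d_ref, tolerance = 1e-12)
  }
})

test_that("repeated runs are bitwise deterministic", {
  s1 <- simulate_biofilm(p0, dose_schedule(), t_final = 5)
  s2 <- simulate_biofilm(p0, dose_schedule(), t_final = 5)
  expect_identical(s1$Lf, s2$Lf)
  expect_identical(s1$S_b, s2$S_b)
})

test_that("simulation results are well-formed", {
  sim <- case_A_sim()
  expect_s3_class(sim, "biofilm_sim")
  expect_true(all(diff(sim$times) > 0))
  expect_equal(sim$times[1], 0)
  expect_equal(sim$Lf[1], p0$Lf0)
  expect_equal(sim$X_t[1, ], p0$X_t0)
  expect_equal(sim$S_t[1, ], p0$S_t0)
  expect_equal(unname(sim$X_b[1, 1, ]), rep(p0$P_b0[1] * p0$rho_L, p0$Nz))
  expect_gte(length(sim$times), 200)
  # non-negativity within solver tolerance
  expect_gt(min(sim$X_b), -1e-6)
  expect_gt(min(sim$S_b), -1e-6)
  df <- as.data.frame(sim)
  expect_equal(nrow(df), length(sim$times))
  expect_true(all(c("time", "Lf_um", "areal_live") %in% names(df)))
})
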