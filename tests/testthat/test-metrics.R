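p0 <- biofilm_params()

make_state <- function(XL, XD, SG, SH, Lf, Nz = length(XL)) {
  list(X_t = c(0, 0), S_t = c(100, 0),
       X_b = rbind(XL, XD), S_b = rbind(SG, SH), Lf = Lf)
}

test_that("areal biomass integrates concentrations over depth", {
  Nz <- 50
  st <- make_state(rep(2e4, Nz), rep(0, Nz), rep(10, Nz), rep(0, Nz), 140e-6)
  ab <- areal_biomass(st)
  expect_equal(ab[["live"]], 2.8)
  expect_equal(ab[["dead"]], 0)
  # linearity: live + dead equals the integral of the total
  st2 <- make_state(runif(Nz, 0, 2e4), runif(Nz, 0, 2e4),
                    rep(10, Nz), rep(0, Nz), 140e-6)
  ab2 <- areal_biomass(st2)
  tot <- sum(st2$X_b[1, ] + st2$X_b[2, ]) * 140e-6 / Nz
  expect_equal(sum(ab2), tot)
})

test_that("log reduction behaves like a log ratio", {
  expect_equal(log_reduction(2.8, 2.8), 0)
  expect_equal(log_reduction(2.8, 0.28), 1)
  expect_equal(log_reduction(10, 0), Inf)
  # antisymmetric under swapping reference and treated
  expect_equal(log_reduction(5, 2), -log_reduction(2, 5))
  expect_error(log_reduction(0, 1), "positive")
})

test_that("planktonic log reduction follows the first-order closed form", {
  expect_equal(planktonic_log_reduction(0, 1), 0)
  expect_equal(planktonic_log_reduction(41.4, 1, 0.5),
               0.5 * 41.4 / log(10))
  expect_equal(planktonic_log_reduction(41.4, 1, 0.5), 8.99, tolerance = 1e-3)
  # linear in duration
  expect_equal(planktonic_log_reduction(100, 3),
               3 * planktonic_log_reduction(100, 1))
})

test_that("penetration depth interpolates the 5% crossing", {
  Nz <- 100
  Lf <- 140e-6
  # uniform profile never crosses: full penetration
  expect_equal(penetration_depth(rep(50, Nz), Lf), Lf)
  # linear profile from surface value to 0 at the base crosses the
  # threshold at (1 - thr) * Lf below the surface
  zc <- ((1:Nz) - 0.5) / Nz
  prof <- 100 * zc
  for (thr in c(0.05, 0.2, 0.5)) {
    got <- penetration_depth(prof, Lf, thr)
    # linear interpolation recovers the exact crossing of thr * S(top)
    expected <- (1 - thr * zc[Nz]) * Lf
    expect_equal(got, expected, tolerance = 1e-9)
  }
  # lower threshold penetrates deeper
  d1 <- penetration_depth(prof, Lf, 0.5)
  d2 <- penetration_depth(prof, Lf, 0.05)
  expect_gt(d2, d1)
  expect_equal(penetration_depth(rep(0, Nz), Lf), 0)
  expect_error(penetration_depth(prof, Lf, 1.5), "threshold")
})

test_that("glucose consumption profile is linear in live biomass", {
  Nz <- 20
  st <- make_state(rep(0, Nz), rep(1e4, Nz), rep(20, Nz), rep(5, Nz), 1e-4)
  expect_equal(consumption_rate_profile(st, p0), rep(0, Nz))
  st1 <- make_state(rep(1e4, Nz), rep(0, Nz), rep(20, Nz), rep(5, Nz), 1e-4)
  st2 <- make_state(rep(2e4, Nz), rep(0, Nz), rep(20, Nz), rep(5, Nz), 1e-4)
  c1 <- consumption_rate_profile(st1, p0)
  c2 <- consumption_rate_profile(st2, p0)
  expect_equal(c2, 2 * c1)
  expect_true(all(c1 >= 0))
})

test_that("mean bulk concentration is a trapezoidal time average", {
  sim <- case_A_sim()
  # constant series averages to itself: tank HP stays at zero undosed
  expect_equal(mean_bulk_concentration(sim, "hp", 10, 50), 0)
  # synthetic linear ramp: average equals the midpoint value
  fake <- sim
  fake$times <- 0:10
  fake$S_t <- cbind(2 * (0:10), 0:10)
  class(fake) <- "biofilm_sim"
  expect_equal(mean_bulk_concentration(fake, "glucose", 0, 10), 10)
  expect_equal(mean_bulk_concentration(fake, "hp", 2, 8), 5)
  expect_error(mean_bulk_concentration(fake, "hp", 8, 2), "empty")
  expect_error(mean_bulk_concentration(fake, "hp", 0, 99), "horizon")
})

test_that("an undosed steady film is fully viable", {
  m <- steady_state_metrics(case_A_sim())
  expect_equal(m$mean_live_fraction, 100, tolerance = 1e-6)
  expect_equal(m$percent_live, 100, tolerance = 1e-6)
  expect_gt(m$areal_live, 0)
  expect_equal(m$areal_dead, 0, tolerance = 1e-6 * m$areal_live)
  expect_lte(m$penetration_glucose, m$Lf_ss)
  expect_false(m$eradicated)
})
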