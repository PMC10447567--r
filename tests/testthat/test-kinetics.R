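p0 <- biofilm_params()

test_that("influent HP follows the piecewise dosing schedule", {
  sch <- dose_schedule(time1 = 2, time2 = 6, dose1 = 500, dose2 = 0)
  expect_equal(influent_hp(sch, 1), 0)
  expect_equal(influent_hp(sch, 4), 500)
  expect_equal(influent_hp(sch, 7), 0)
  # closed interval at the switch instants
  expect_equal(influent_hp(sch, c(2, 6)), c(500, 500))
  cont <- dose_schedule(dose1 = 300, dose2 = 300)
  expect_equal(influent_hp(cont, c(0, 2, 100)), c(0, 300, 300))
  expect_error(dose_schedule(time1 = 6, time2 = 2), "time1")
  expect_error(dose_schedule(dose1 = -1), "non-negative")
})

test_that("Monod growth rate saturates and halves at K_M", {
  expect_equal(growth_rate(0, p0), 0)
  expect_equal(growth_rate(p0$K_M, p0), p0$mu_max / 2)  # 4.8 /d exactly
  expect_equal(growth_rate(1e9, p0), p0$mu_max, tolerance = 1e-6)
  s <- seq(0, 50, by = 0.5)
  expect_true(all(diff(growth_rate(s, p0)) > 0))
  expect_true(all(growth_rate(s, p0) <= p0$mu_max))
  expect_error(growth_rate(-1, p0), "non-negative")
})

test_that("disinfection converts live to dead biomass without loss", {
  # direct arithmetic: X_L = 1, S_G = 0, S_H = 10, k_dis = 0.5
  r <- particulate_rates(1, 0, 0, 10, p0)
  expect_equal(r$live, -5)
  expect_equal(r$dead, 5)
  # no biocide: pure Monod growth, nothing dies
  r <- particulate_rates(3, 1, 20, 0, p0)
  expect_equal(r$dead, 0)
  expect_equal(r$live, growth_rate(20, p0) * 3)
  # nothing to grow or kill
  r <- particulate_rates(0, 2, 50, 100, p0)
  expect_equal(r$live, 0)
  expect_equal(r$dead, 0)
  # conservation and degree-1 homogeneity across random states
  set.seed(42)
  for (i in 1:20) {
    XL <- runif(1, 0, 3e4); XD <- runif(1, 0, 3e4)
    SG <- runif(1, 0, 200); SH <- runif(1, 0, 1000)
    r1 <- particulate_rates(XL, XD, SG, SH, p0)
    expect_equal(r1$live + r1$dead, growth_rate(SG, p0) * XL)
    lam <- runif(1, 0.1, 10)
    r2 <- particulate_rates(lam * XL, lam * XD, SG, SH, p0)
    expect_equal(r2$live, lam * r1$live)
    expect_equal(r2$dead, lam * r1$dead)
    s1 <- solute_rates(XL, XD, SG, SH, p0)
    s2 <- solute_rates(lam * XL, lam * XD, SG, SH, p0)
    expect_equal(s2$glucose, lam * s1$glucose)
    expect_equal(s2$hp, lam * s1$hp)
  }
})

test_that("solute consumption rates follow yield and neutralization laws", {
  r <- solute_rates(0, 0, 50, 100, p0)
  expect_equal(r$glucose, 0)
  expect_equal(r$hp, 0)
  # X_L = 2, S_G = K_M: -(1/0.26) * 4.8 * 2
  r <- solute_rates(2, 0, 5, 0, p0)
  expect_equal(r$glucose, -(1 / 0.26) * 4.8 * 2, tolerance = 1e-12)
  # knockout of both neutralization routes silences HP consumption
  pk <- biofilm_params(k_B_L = 0, k_B_D = 0)
  expect_equal(solute_rates(1e4, 1e4, 10, 500, pk)$hp, 0)
  # rates are never positive
  set.seed(7)
  for (i in 1:10) {
    r <- solute_rates(runif(1, 0, 3e4), runif(1, 0, 3e4),
                      runif(1, 0, 200), runif(1, 0, 2e4), p0)
    expect_lte(r$glucose, 0)
    expect_lte(r$hp, 0)
  }
})

test_that("detachment velocity is quadratic in thickness", {
  expect_equal(detachment_velocity(0, p0), 0)
  expect_equal(detachment_velocity(150e-6, p0), 2.25e-4)
  lf <- runif(5, 1e-6, 5e-4)
  expect_equal(detachment_velocity(2 * lf, p0),
               4 * detachment_velocity(lf, p0))
})

test_that("parameter validation rejects inconsistent inputs", {
  expect_error(biofilm_params(K_M = -1), "K_M")
  expect_error(biofilm_params(Nz = 1), "Nz")
  expect_error(biofilm_params(nonsense = 3), "unknown parameter")
  expect_error(biofilm_params(P_b0 = c(0.7, 0.5)), "sum")
  expect_silent(p <- biofilm_params(k_B_D = 0))
  expect_equal(p$k_B_D, 0)
})
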