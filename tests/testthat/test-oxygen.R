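# steady-state oxygen diffusion-consumption model

test_that("partial pressure follows the humidified-atmosphere relation", {
  p <- oxygen_params()
  expect_equal(partial_pressure_o2(p), 0.21 * (760 - 47.067),
               tolerance = 1e-9)
  expect_equal(partial_pressure_o2(oxygen_params(F_O2 = 1e-12)), 0,
               tolerance = 1e-9)
  expect_equal(partial_pressure_o2(oxygen_params(F_O2 = 0.9999,
                                                 P_H2O = 1e-9)),
               0.9999 * 760, tolerance = 1e-6)
  expect_error(partial_pressure_o2(oxygen_params(P_H2O = 800)), "P_ATM")
})

test_that("surface concentration obeys Henry's law", {
  p <- oxygen_params()
  expect_equal(surface_concentration(p), 149.71593 * 0.0031,
               tolerance = 1e-5)
  expect_equal(surface_concentration(oxygen_params(Kc = 2 / 0.0031)),
               surface_concentration(p) / 2, tolerance = 1e-12)
  # independent of the consumption rate
  expect_equal(surface_concentration(oxygen_params(r = 0.1)),
               surface_concentration(p), tolerance = 1e-12)
})

test_that("zero consumption gives a flat profile at the surface value", {
  prof <- concentration_profile(oxygen_params(r = 0, x_b = 10))
  expect_equal(prof$profile$concentration_ml_dL,
               rep(prof$surface_ml_dL, nrow(prof$profile)),
               tolerance = 1e-12)
})

test_that("the profile is linear with the flux-balance slope", {
  p <- oxygen_params(x_b = 10)
  prof <- concentration_profile(p)
  drop <- prof$surface_ml_dL - tail(prof$profile$concentration_ml_dL, 1)
  expected <- 10 * (p$r / 60) / (p$D * p$A) * 100  # ml O2/dL
  expect_equal(drop, expected, tolerance = 1e-10)
})

test_that("closed form matches the finite-difference oracle within 0.1%", {
  for (m in c(1, 5, 20, 40)) {
    for (xb in c(1, 5, 10)) {
      p <- oxygen_params(r = m * 0.023e-5, x_b = xb)
      an <- concentration_profile(p, n_depths = 101)
      fd <- concentration_profile_fd(p, n = 101)
      expect_lt(max(abs(fd$concentration_ml_dL -
                          an$profile$concentration_ml_dL)) /
                  an$surface_ml_dL, 1e-3)
    }
  }
})

test_that("the two coherent unit systems agree to 1e-9", {
  p <- oxygen_params(x_b = 10)
  a <- concentration_profile(p, units = "cgs")
  b <- concentration_profile(p, units = "si")
  expect_equal(a$profile$concentration_ml_dL,
               b$profile$concentration_ml_dL, tolerance = 1e-9)
})

test_that("consumption sweep is monotone with an analytic threshold depth", {
  p <- oxygen_params()
  sw <- sweep_consumption(p, multipliers = c(1, 10, 40),
                          heights_mm = c(0, 20, 60, 100))
  g <- sw$grid
  # monotone decreasing in both multiplier and height
  for (m in unique(g$multiplier)) {
    expect_true(all(diff(g$bottom_ml_dL[g$multiplier == m]) <= 0))
  }
  for (h in unique(g$height_mm)[-1]) {
    expect_true(all(diff(g$bottom_ml_dL[g$height_mm == h]) <= 0))
  }
  # zero multiplier: no height dependence
  sw0 <- sweep_consumption(p, multipliers = 0, heights_mm = c(0, 50, 100))
  expect_equal(diff(range(sw0$grid$bottom_ml_dL)), 0, tolerance = 1e-12)
  # threshold depth from inverting the linear profile
  slope1 <- (p$r / 60) / (p$D * p$A) * 100
  expected <- 10 * (sw$surface_ml_dL - sw$phi_1pct_ml_dL) / (10 * slope1)
  expect_equal(sw$threshold$depth_1pct_mm[sw$threshold$multiplier == 10],
               expected, tolerance = 1e-9)
})

test_that("hydrostatic reservoir pressure is rho g h", {
  expect_equal(reservoir_pressure(0.1), 1000 * 9.81 * 0.1, tolerance = 1e-12)
  expect_equal(reservoir_pressure(0.0102), 1000 * 9.81 * 0.0102,
               tolerance = 1e-12)  # ~100 Pa for a ~1 cm head
})

test_that("parameter validation enforces physical ranges", {
  expect_error(oxygen_params(Kc = -1), "Kc")
  expect_error(oxygen_params(F_O2 = 1.5), "F_O2")
  expect_error(oxygen_params(r = -1), "r")
})
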