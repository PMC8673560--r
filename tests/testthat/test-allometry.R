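# power-law fitting, bootstrap, and the curve-collapse diagnostic

test_that("noiseless power laws are recovered exactly", {
  f2 <- fit_power_law(c(1, 2, 4, 8), c(1, 4, 16, 64))
  expect_equal(f2$exponent_a, 2, tolerance = 1e-10)
  expect_equal(f2$r_squared, 1, tolerance = 1e-10)

  f1 <- fit_power_law(c(1, 2, 4), 3 * c(1, 2, 4))
  expect_equal(f1$exponent_a, 1, tolerance = 1e-10)
  expect_equal(f1$prefactor_c, 3, tolerance = 1e-10)

  fn <- fit_power_law(c(1, 2, 4, 8), c(1, 4, 16, 64), method = "nls")
  expect_equal(fn$exponent_a, 2, tolerance = 1e-6)
})

test_that("input validation rejects degenerate data", {
  expect_error(fit_power_law(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_power_law(c(1, -2, 3), c(1, 2, 3)), "positive")
  expect_error(fit_power_law(c(1, 2, 3), c(1, 2)), "equal length")
})

test_that("rescaling x by k multiplies c by k^(-a) and leaves a fixed", {
  x <- c(1.2, 1.7, 2.4, 3.1, 4.4)
  y <- 0.9 * x^1.8 * exp(c(0.02, -0.03, 0.01, 0.015, -0.01))
  f <- fit_power_law(x, y)
  k <- 3.7
  fk <- fit_power_law(k * x, y)
  expect_equal(fk$exponent_a, f$exponent_a, tolerance = 1e-8)
  expect_equal(fk$prefactor_c, f$prefactor_c * k^(-f$exponent_a),
               tolerance = 1e-8)
})

test_that("bootstrap CI is seeded, degenerate for exact data, and guarded", {
  x <- c(1, 2, 4, 8)
  y <- x^2
  ci <- bootstrap_ci(x, y, n_boot = 200, seed = 42)
  expect_equal(ci, c(2, 2), tolerance = 1e-10)
  expect_identical(bootstrap_ci(x, y, 200, 42), ci)
  expect_error(bootstrap_ci(x, y, n_boot = 50), "100")
})

test_that("bootstrap CI covers the true exponent in most replicates", {
  a_true <- 1.67
  x <- rep(c(1.3, 1.7, 2.1, 2.6), each = 3)
  hits <- withr::with_seed(99, {
    vapply(1:100, function(b) {
      y <- x^a_true * exp(rnorm(length(x), 0, 0.1))
      ci <- bootstrap_ci(x, y, n_boot = 200, seed = b)
      ci[1] <= a_true && a_true <= ci[2]
    }, logical(1))
  })
  expect_gte(sum(hits), 90)
})

test_that("mean recovered exponent is unbiased under lognormal noise", {
  a_true <- 1.67
  x <- rep(1 + 0.018 * c(24, 48, 72), each = 3)
  a_hat <- withr::with_seed(7, {
    vapply(1:50, function(b) {
      y <- x^a_true * exp(rnorm(length(x), 0, 0.1))
      fit_power_law(x, y)$exponent_a
    }, numeric(1))
  })
  expect_lt(abs(mean(a_hat) - a_true), 0.05)
})

test_that("collapse test separates shared from divergent scaling", {
  x <- c(1.2, 1.6, 2.1, 2.8)
  same <- fit_power_law(x, x^1.67)
  res <- collapse_test(list(`-100` = same, `-400` = same, `-1000` = same))
  expect_equal(res$delta_a_max, 0, tolerance = 1e-12)
  expect_true(res$pass)

  shifted <- fit_power_law(x, x^2.67)
  res2 <- collapse_test(list(`-100` = same, `-1000` = shifted))
  expect_gt(res2$delta_a_max, 0.9)
  expect_false(res2$pass)
})
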