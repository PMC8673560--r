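# generator: canonical topology, growth schedules, rasterization

test_that("canonical tree has the stereotyped E12.5 topology", {
  tree <- cached_canonical(11)
  seg <- tree$segments
  expect_equal(nrow(seg), 12)
  expect_equal(sum(seg$is_terminal), 9)
  l_id <- seg$segment_id[seg$label == "L"]
  r_id <- seg$segment_id[seg$label == "R"]
  l_kids <- seg$label[!is.na(seg$parent_id) & seg$parent_id == l_id]
  r_kids <- seg$label[!is.na(seg$parent_id) & seg$parent_id == r_id]
  expect_length(l_kids, 5)
  expect_setequal(l_kids, c("L1", "L2", "L3", "L4", "L5"))
  expect_setequal(r_kids, c("RCd", "RAc", "RMd", "RCr"))
  expect_silent(validate_airway_tree(tree))
})

test_that("canonical geometry is deterministic in the seed", {
  a <- build_canonical_tree(growth_config(rng_seed = 4))
  b <- build_canonical_tree(growth_config(rng_seed = 4))
  expect_identical(a$segments$points, b$segments$points)
  expect_identical(a$segments$radii, b$segments$radii)
  c2 <- build_canonical_tree(growth_config(rng_seed = 5))
  expect_false(identical(a$segments$points, c2$segments$points))
})

test_that("zero culture time returns the tree unchanged", {
  cfg <- growth_config(rng_seed = 3, time_h = 0)
  tree <- build_canonical_tree(cfg)
  expect_identical(grow_tree(tree, cfg), tree)
})

test_that("terminal branch count rises with time and falls with pressure", {
  tree <- cached_canonical(6)
  counts <- vapply(c(24, 48, 72), function(t) {
    g <- grow_tree(tree, growth_config(rng_seed = 6, time_h = t))
    sum(g$segments$is_terminal)
  }, numeric(1))
  expect_true(all(diff(counts) > 0))

  n_soft <- sum(grow_tree(tree, growth_config(rng_seed = 6, time_h = 48,
                                              pressure_Pa = -100)
                          )$segments$is_terminal)
  n_hard <- sum(grow_tree(tree, growth_config(rng_seed = 6, time_h = 48,
                                              pressure_Pa = -1000)
                          )$segments$is_terminal)
  expect_lt(n_hard, n_soft)
})

test_that("growth calibration: one scaling curve, pressure-independent area", {
  tree <- cached_canonical(2)
  a0 <- analytic_surface_area(tree)
  rows <- list()
  for (p in c(-100, -400, -1000)) {
    for (t in c(24, 48, 72)) {
      g <- grow_tree(tree, growth_config(rng_seed = 2, time_h = t,
                                         pressure_Pa = p))
      m <- analytic_metrics(g)
      rows[[length(rows) + 1]] <- data.frame(
        p = p, t = t,
        fold_area = m$surface_area_um2 / a0,
        fold_branches = m$terminal_branch_count / 9
      )
    }
  }
  d <- do.call(rbind, rows)

  # area schedule: < 2 percent spread across pressures at fixed time,
  # linear in time with R^2 > 0.99
  for (t in unique(d$t)) {
    fa <- d$fold_area[d$t == t]
    expect_lt(diff(range(fa)) / mean(fa), 0.02)
  }
  lf <- lm(fold_area ~ t, data = rbind(d, data.frame(p = NA, t = 0,
                                                     fold_area = 1,
                                                     fold_branches = 1)))
  expect_gt(summary(lf)$r.squared, 0.99)

  # collapse: pooled log-log slope within 0.05 of the configured
  # exponent, with single-curve fit quality at the observed level
  fit <- fit_power_law(d$fold_area, d$fold_branches)
  expect_lt(abs(fit$exponent_a - 1.67), 0.05)
  expect_gt(fit$r_squared, 0.97)
})

test_that("RCr radius follows the pressure/time schedule", {
  tree <- cached_canonical(8)
  rcr <- function(g) {
    i <- match("RCr", g$segments$label)
    airwaymorph:::profile_window_mean(g$segments$points[[i]],
                                      g$segments$radii[[i]], c(0.1, 0.6))
  }
  g100 <- grow_tree(tree, growth_config(rng_seed = 8, time_h = 72,
                                        pressure_Pa = -100))
  g1000 <- grow_tree(tree, growth_config(rng_seed = 8, time_h = 72,
                                         pressure_Pa = -1000))
  # schedule: 0.4 / 0.8 of the initial radius -> ratio 1/2
  expect_equal(rcr(g1000) / rcr(g100), 0.5, tolerance = 0.02)
})

test_that("invalid schedules are rejected", {
  expect_error(growth_config(time_h = -1), "time_h")
  expect_error(
    growth_config(rcr_radius_schedule = function(p, t) 0, time_h = 24),
    "fraction"
  )
  expect_error(
    growth_config(branching_rate_schedule = function(p) -1),
    "rate"
  )
})

test_that("rasterized capsule volume matches the closed form", {
  cyl <- phantom_cylinder(radius = 10, length = 200)
  v <- rasterize(cyl, 2)
  meas <- region_volume(v)
  truth <- pi * 10^2 * 200 + 4 / 3 * pi * 10^3
  expect_equal(meas, truth, tolerance = 0.05)
  expect_equal(n_components(v), 1)
})

test_that("rasterization edge cases behave", {
  expect_equal(sum(as.integer(rasterize(empty_airway_tree())$mask)), 0)
  expect_error(rasterize(phantom_cylinder(radius = 3), spacing_um = 2),
               "2 voxels")
  v <- rasterize(cached_canonical(1), 3)
  expect_equal(n_components(v), 1)
  # determinism: identical config -> bit-identical volume end to end
  v2 <- rasterize(build_canonical_tree(growth_config(rng_seed = 1)), 3)
  expect_identical(v$mask, v2$mask)
})

test_that("closed-form metrics match hand calculations", {
  cyl <- phantom_cylinder(radius = 10, length = 100)
  expect_equal(analytic_volume(cyl), pi * 100 * 100 + 4 / 3 * pi * 1000,
               tolerance = 1e-10)
  expect_equal(analytic_surface_area(cyl), 2 * pi * 10 * 100 + 4 * pi * 100,
               tolerance = 1e-10)
  tree <- cached_canonical(9)
  expect_equal(analytic_metrics(tree)$terminal_branch_count, 9)
})
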