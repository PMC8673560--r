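# voxel morphometry against closed forms and the generator oracle

test_that("digital ball reproduces sphere area and volume", {
  v <- digital_ball(radius = 50, spacing = 2)
  expect_equal(surface_area(v), 4 * pi * 50^2, tolerance = 0.05)
  expect_equal(region_volume(v), 4 / 3 * pi * 50^3, tolerance = 0.03)
})

test_that("surface area is additive over disjoint components", {
  v <- digital_two_balls(r1 = 30, r2 = 20, gap = 40, spacing = 2)
  expect_equal(n_components(v), 2)
  expect_equal(surface_area(v), 4 * pi * (30^2 + 20^2), tolerance = 0.05)
  expect_equal(region_volume(v), 4 / 3 * pi * (30^3 + 20^3),
               tolerance = 0.03)
})

test_that("empty volume measures zero with a warning", {
  m <- array(raw(1), dim = c(6, 6, 6))
  v <- labeled_volume(m, 2)
  expect_warning(a <- surface_area(v), "empty")
  expect_equal(a, 0)
  expect_equal(region_volume(v), 0)
})

test_that("voxel measurements agree with the closed-form tree oracle", {
  tree <- cached_canonical(6)
  v <- rasterize(tree, 2)
  expect_equal(surface_area(v), analytic_surface_area(tree),
               tolerance = 0.10)
  expect_equal(region_volume(v), analytic_volume(tree), tolerance = 0.05)

  g <- grow_tree(tree, growth_config(rng_seed = 6, time_h = 48))
  v2 <- rasterize(g, 2.5)
  expect_equal(surface_area(v2), analytic_surface_area(g), tolerance = 0.10)
  expect_equal(region_volume(v2), analytic_volume(g), tolerance = 0.05)
})

test_that("fold-change annotation normalizes against the baseline record", {
  rec <- tibble::tibble(
    record_id = c("base", "double"),
    surface_area_um2 = c(100, 200),
    volume_um3 = c(10, 30),
    terminal_branch_count = c(9, 18)
  )
  out <- fold_change_series(rec, "base")
  expect_equal(out$fold_area, c(1, 2))
  expect_equal(out$fold_branches, c(1, 2))
  expect_equal(out$fold_volume, c(1, 3))

  expect_error(fold_change_series(rec, "missing"), "not found")
  rec0 <- rec
  rec0$surface_area_um2[1] <- 0
  expect_error(fold_change_series(rec0, "base"), "> 0")
})
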