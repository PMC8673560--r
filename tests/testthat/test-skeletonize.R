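# centerline extraction: topology, radii, pruning

test_that("a digital cylinder skeletonizes to one axial segment", {
  v <- rasterize(phantom_cylinder(radius = 10, length = 200), 2)
  sk <- prune_spurs(skeletonize(v))
  expect_equal(sum(sk$nodes$kind == "junction"), 0)
  expect_equal(sum(sk$nodes$kind == "endpoint"), 2)
  expect_equal(nrow(sk$segments), 1)
  # distance-transform radius within one voxel of truth
  expect_lt(abs(mean(sk$points$radius) - 10), 2)
})

test_that("a single foreground voxel yields a single skeleton point", {
  m <- array(raw(1), dim = c(7, 7, 7))
  m[4, 4, 4] <- as.raw(1)
  sk <- skeletonize(labeled_volume(m, 2))
  expect_equal(nrow(sk$points), 1)
  expect_equal(nrow(sk$segments), 1)
})

test_that("empty foreground raises an explicit error", {
  m <- array(raw(1), dim = c(5, 5, 5))
  expect_error(skeletonize(labeled_volume(m, 2)), "empty foreground")
})

test_that("a Y-shaped tube resolves to 1 junction, 3 endpoints, 3 segments", {
  v <- rasterize(phantom_y_tube(), 2)
  sk <- prune_spurs(skeletonize(v))
  expect_equal(sum(sk$nodes$kind == "junction"), 1)
  expect_equal(sum(sk$nodes$kind == "endpoint"), 3)
  expect_equal(nrow(sk$segments), 3)
})

test_that("skeleton of a tree volume is connected and acyclic", {
  v <- rasterize(build_canonical_tree(growth_config(rng_seed = 12)), 2.5)
  sk <- skeletonize(v)
  # Euler characteristic of the graph: components - independent loops = 1
  expect_equal(nrow(sk$points) - nrow(sk$edges), 1)
})

test_that("pruning removes sub-radius spurs and is a fixed point", {
  # synthetic skeleton: a 30-point path with a one-point side spur
  n <- 30
  pts <- tibble::tibble(point_id = 1:(n + 1),
                        x = c((0:(n - 1)) * 5, 70),
                        y = c(rep(0, n), 5),
                        z = 0,
                        radius = c(rep(8, n), 8))
  edges <- rbind(cbind(1:(n - 1), 2:n), c(15, n + 1))
  sk <- airwaymorph:::skeleton_graph_core(pts, edges, spacing_um = rep(2, 3))
  expect_equal(nrow(sk$segments), 3)  # spur splits the path
  pruned <- prune_spurs(sk)
  expect_equal(nrow(pruned$segments), 1)
  expect_equal(sum(pruned$nodes$kind == "endpoint"), 2)
  # fixed point: pruning again changes nothing
  expect_identical(prune_spurs(pruned)$points, pruned$points)
})

test_that("pruned topology equals generator ground truth", {
  tree <- cached_canonical(5)
  sk <- cached_skel(5, 2.5)
  topo <- airwaymorph:::tree_skeleton_topology(tree)
  expect_equal(sum(sk$nodes$kind == "junction"), topo$n_junction)
  expect_equal(sum(sk$nodes$kind == "endpoint"), topo$n_endpoint)
  expect_equal(nrow(sk$segments), topo$n_run)
})

test_that("radius_along averages the profile over an arclength window", {
  sk <- line_skeleton(seq(20, 10, length.out = 41))
  expect_equal(radius_along(sk, 1, c(0, 1)), 15, tolerance = 0.01)
  # symmetry of the linear taper about the midpoint
  expect_equal(radius_along(sk, 1, c(0.25, 0.75)), 15, tolerance = 0.01)
  skc <- line_skeleton(rep(12, 41))
  expect_equal(radius_along(skc, 1, c(0.2, 0.9)), 12, tolerance = 1e-6)
  expect_error(radius_along(skc, 1, c(0.7, 0.2)), "window")
  expect_error(radius_along(skc, 99), "unknown segment")
})

test_that("estimated cylinder radius converges with resolution", {
  errs <- vapply(c(4, 2, 1), function(sp) {
    v <- rasterize(phantom_cylinder(radius = 10, length = 120), sp)
    sk <- prune_spurs(skeletonize(v))
    abs(radius_along(sk, 1, c(0.15, 0.85)) - 10)
  }, numeric(1))
  expect_lt(errs[3], 1)          # within one voxel at the finest spacing
  expect_lt(errs[3], errs[1] + 0.25)  # no worse than the coarsest
})

test_that("anisotropic spacing is handled in physical units", {
  # cylinder along y rasterized with anisotropic voxels
  v <- rasterize(phantom_cylinder(radius = 12, length = 150),
                 spacing_um = c(2, 3, 2))
  sk <- prune_spurs(skeletonize(v))
  expect_equal(nrow(sk$segments), 1)
  expect_lt(abs(radius_along(sk, 1, c(0.2, 0.8)) - 12), 3)
})
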