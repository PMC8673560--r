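# shared fixtures, all generated in code

# digital ball mask centred in a cube, as a labeled_volume
digital_ball <- function(radius = 50, spacing = 2, centre_offset = c(0, 0, 0)) {
  n <- ceiling(2 * radius / spacing) + 7
  ax <- (seq_len(n) - (n + 1) / 2) * spacing
  g <- expand.grid(x = ax, y = ax, z = ax)
  inside <- (g$x - centre_offset[1])^2 + (g$y - centre_offset[2])^2 +
    (g$z - centre_offset[3])^2 <= radius^2
  m <- array(as.raw(as.integer(inside)), dim = c(n, n, n))
  labeled_volume(m, spacing)
}

# two disjoint balls in one volume
digital_two_balls <- function(r1 = 30, r2 = 20, gap = 40, spacing = 2) {
  n <- ceiling((2 * r1 + 2 * r2 + gap) / spacing) + 10
  ny <- ceiling(2 * r1 / spacing) + 8
  ax <- seq_len(n) * spacing
  ay <- seq_len(ny) * spacing
  c1 <- c(r1 + 4 * spacing, mean(ay), mean(ay))
  c2 <- c(c1[1] + r1 + gap + r2, mean(ay), mean(ay))
  g <- expand.grid(x = ax, y = ay, z = ay)
  inside <- ((g$x - c1[1])^2 + (g$y - c1[2])^2 + (g$z - c1[3])^2 <= r1^2) |
    ((g$x - c2[1])^2 + (g$y - c2[2])^2 + (g$z - c2[3])^2 <= r2^2)
  m <- array(as.raw(as.integer(inside)), dim = c(n, ny, ny))
  labeled_volume(m, spacing)
}

# linearly tapered tube tree (r0 at origin end, r1 at tip)
tapered_tube <- function(r0 = 20, r1 = 10, length = 200) {
  pts <- cbind(0, seq(0, -length, length.out = 21), 0)
  airwaymorph:::new_airway_tree(tibble::tibble(
    segment_id = 1L, parent_id = NA_integer_, label = "tube",
    generation = 0L, is_terminal = TRUE, attach_frac = NA_real_,
    points = list(pts), radii = list(seq(r0, r1, length.out = 21))
  ))
}

# straight-line synthetic skeleton with a chosen radius profile (no voxels)
line_skeleton <- function(radii, step = 5) {
  n <- length(radii)
  pts <- tibble::tibble(
    point_id = seq_len(n),
    x = (seq_len(n) - 1) * step, y = 0, z = 0,
    radius = radii
  )
  edges <- cbind(seq_len(n - 1), 2:n)
  airwaymorph:::skeleton_graph_core(pts, edges, spacing_um = rep(step, 3))
}

# mirror an airway tree through the x = 0 plane
mirror_tree_x <- function(tree) {
  tree$segments$points <- lapply(tree$segments$points, function(p) {
    p[, 1] <- -p[, 1]
    p
  })
  tree
}

canonical_label_set <- c("Tr", "R", "L", "RCd", "RAc", "RMd", "RCr",
                        "L1", "L2", "L3", "L4", "L5")

# canonical trees and their skeletons are pure functions of (seed,
# spacing); cache them across test files to keep the suite fast
.fixture_cache <- new.env(parent = emptyenv())

cached_canonical <- function(seed) {
  key <- paste0("tree_", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- build_canonical_tree(growth_config(rng_seed = seed))
  }
  .fixture_cache[[key]]
}

cached_skel <- function(seed, spacing = 2.5) {
  key <- paste0("skel_", seed, "_", spacing)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <-
      prune_spurs(skeletonize(rasterize(cached_canonical(seed), spacing)))
  }
  .fixture_cache[[key]]
}
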