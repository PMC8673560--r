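#' Skeletonize a binary airway volume
#'
#' Extracts the topological centerline of the foreground by
#' distance-ordered homotopic thinning: voxels are deleted in order of
#' increasing Euclidean distance to the background, a voxel is deleted
#' only if it is a simple point (deletion preserves the number of
#' 26-connected foreground and 6-connected background components in its
#' neighbourhood), and endpoints are preserved. The result is a
#' 1-voxel-wide, 26-connected centerline homotopic to the input; for a
#' simply connected solid it is a tree. The per-point radius is the
#' Euclidean distance transform at the centerline voxel (computed in
#' physical units, so anisotropic spacing is handled exactly), corrected
#' by half a voxel for the digitization bias of the background boundary.
#'
#' @param volume a [labeled_volume()] with at least one foreground voxel.
#' @return a `skeleton_graph`: points with radii, junction/endpoint nodes,
#'   and maximal junction-free segments.
#' @export
skeletonize <- function(volume) {
  stopifnot(inherits(volume, "labeled_volume"))
  dims <- dim(volume$mask)
  nfg <- .count_foreground_cpp(volume$mask)
  if (nfg == 0) stop("cannot skeletonize a volume with empty foreground")
  # chi == 1 on the raw mask certifies a handle-free solid without
  # enclosed cavities, so any skeleton cycle found later is a
  # 26-connectivity digitization artifact; otherwise fill cavities
  # (thinning would preserve a shell around them) and re-examine
  chi_raw <- .euler_characteristic_cpp(volume$mask, dims)
  if (abs(chi_raw - 1) < 0.5) {
    mask <- volume$mask
    solid_is_tree <- TRUE
  } else {
    mask <- .fill_cavities_cpp(volume$mask, dims)
    dim(mask) <- dims
    solid_is_tree <- .count_components_cpp(mask, dims, 6L) == 1 &&
      abs(.euler_characteristic_cpp(mask, dims) - 1) < 0.5
  }
  res <- .skeletonize_cpp(mask, dims, volume$spacing_um)
  coords <- res$coords
  sp <- volume$spacing_um
  radius <- pmax(res$edt - 0.5 * mean(sp), 0.25 * min(sp))
  pos <- sweep(sweep(coords - 1, 2, sp, `*`), 2, volume$origin_um, `+`)
  points <- tibble(
    point_id = seq_len(nrow(coords)),
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    radius = radius,
    ix = coords[, 1], iy = coords[, 2], iz = coords[, 3]
  )
  edges <- voxel_adjacency_edges(coords, dims)
  edges <- clean_triangle_edges(pos, edges)
  edges <- break_digitization_cycles(edges, nrow(points), solid_is_tree)
  skel <- skeleton_graph_core(points, edges, spacing_um = sp,
                              origin_um = volume$origin_um)
  skel
}

# 26-neighbour edges among skeleton voxels via linear-index matching
voxel_adjacency_edges <- function(coords, dims) {
  if (nrow(coords) < 2) return(matrix(integer(), 0, 2))
  nx <- dims[1]; ny <- dims[2]
  lin <- (coords[, 1] - 1) + nx * ((coords[, 2] - 1) + ny * (coords[, 3] - 1))
  out <- vector("list", 13)
  k <- 0
  for (dz in 0:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && (dy < 0 || (dy == 0 && dx <= 0))) next
    k <- k + 1
    # guard against wrap-around at the volume faces
    ok <- coords[, 1] + dx >= 1 & coords[, 1] + dx <= dims[1] &
      coords[, 2] + dy >= 1 & coords[, 2] + dy <= dims[2] &
      coords[, 3] + dz >= 1 & coords[, 3] + dz <= dims[3]
    nbr <- lin + dx + nx * (dy + ny * dz)
    hit <- match(nbr, lin)
    sel <- ok & !is.na(hit)
    out[[k]] <- cbind(which(sel), hit[sel])
  }
  edges <- do.call(rbind, out)
  if (is.null(edges)) matrix(integer(), 0, 2) else edges
}

#' Prune short terminal spurs from a skeleton
#'
#' Thinning leaves short terminal twigs near caps and junction blobs.
#' A terminal segment is removed when its protrusion beyond the junction
#' blob -- its length minus the distance-transform radius `r_junction` at
#' its junction (segment lengths are measured from the junction-cluster
#' centroid, i.e. from inside the parent tube) -- is shorter than
#' `max(min_length_um, prune_factor * r_junction)`: a bud poking out less
#' than half the local tube radius is a thinning artifact, not a branch.
#' Removal iterates to convergence and never disconnects the graph (only
#' leaf segments are removed, and a skeleton consisting of a single
#' segment is returned unchanged).
#'
#' @param skel a `skeleton_graph`.
#' @param min_length_um absolute length floor; defaults to 2 voxels.
#' @param prune_factor multiple of the local junction radius below which a
#'   terminal segment is considered a spur.
#' @return the pruned `skeleton_graph`.
#' @export
prune_spurs <- function(skel, min_length_um = NULL, prune_factor = 0.5) {
  sp <- skel$spacing_um
  if (is.null(min_length_um)) {
    min_length_um <- if (all(is.finite(sp))) 2 * max(sp) else 0
  }
  for (iter in 1:100) {
    segs <- skel$segments
    if (nrow(segs) <= 1) return(skel)
    kind <- setNames(skel$nodes$kind, skel$nodes$node_id)
    nrad <- setNames(skel$nodes$radius, skel$nodes$node_id)
    drop_points <- integer()
    for (i in seq_len(nrow(segs))) {
      k1 <- kind[[as.character(segs$node1[i])]]
      k2 <- kind[[as.character(segs$node2[i])]]
      if (sum(c(k1, k2) == "endpoint") != 1) next
      jn <- if (k1 == "junction") segs$node1[i] else segs$node2[i]
      r_j <- nrad[[as.character(jn)]]
      thr <- max(min_length_um, prune_factor * r_j)
      if (segs$length_um[i] - r_j < thr) {
        drop_points <- c(drop_points, segs$point_ids[[i]])
      }
    }
    if (length(drop_points) == 0) return(skel)
    keep <- setdiff(seq_len(nrow(skel$points)), drop_points)
    if (length(keep) == 0) return(skel)
    relabel <- rep(NA_integer_, nrow(skel$points))
    relabel[keep] <- seq_along(keep)
    pts <- skel$points[keep, ]
    pts$point_id <- seq_len(nrow(pts))
    e <- skel$edges
    e <- e[e[, 1] %in% keep & e[, 2] %in% keep, , drop = FALSE]
    e <- cbind(relabel[e[, 1]], relabel[e[, 2]])
    skel <- skeleton_graph_core(pts, e, spacing_um = sp,
                                origin_um = skel$origin_um)
  }
  skel
}

#' Mean radius over an arclength window of a skeleton segment
#'
#' @param skel a `skeleton_graph`.
#' @param segment_id segment identifier.
#' @param window arclength-fraction window `c(f_lo, f_hi)` measured from
#'   the segment's node1 end, with `0 <= f_lo < f_hi <= 1`.
#' @return mean radius in micrometres.
#' @export
radius_along <- function(skel, segment_id, window = c(0, 1)) {
  if (!(window[1] >= 0 && window[1] < window[2] && window[2] <= 1)) {
    stop("window must satisfy 0 <= f_lo < f_hi <= 1")
  }
  prof <- segment_profile(skel, segment_id)
  profile_window_mean(prof$pts, prof$radii, window)
}
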