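# Synthetic airway generator: canonical E12.5 topology and seeded growth.
#
# Coordinate convention: +y is cranial; the trachea starts at the origin and
# runs caudally (-y), so the root endpoint is the topmost skeleton point,
# matching confocal images with the trachea at the top. The right primary
# bronchus extends toward -x, the left toward +x.

# straight polyline from start along dir, sampled roughly every `step` um
make_polyline <- function(start, dir, length, step = 12) {
  n <- max(3, ceiling(length / step) + 1)
  s <- seq(0, length, length.out = n)
  sweep(outer(s, unit3(dir)), 2, start, `+`)
}

# linear taper from r0 to taper * r0 along an m-point polyline
make_radii <- function(n, r0, taper) {
  seq(r0, r0 * taper, length.out = n)
}

# Worst dangerous surface gap (um) of a candidate polyline against the
# existing tree. A tube contact is topologically harmless when the contact
# region is contiguous with the parent solid (the union stays simply
# connected: a "webbed" junction); it creates a handle -- a loop in the
# skeleton -- only when the contact is separated from the parent. Rules:
#   parent:  geometry within a junction ball around the attachment is not
#            tested (the bud emerges from inside); any contact beyond the
#            ball (the branch folding back onto its parent) is dangerous;
#   twin sibling at the same attachment: contact whose midpoint is inside
#            the shared junction ball is safe;
#   any segment: a contact pair is dangerous only if the midpoint of the
#            overlap lies > 1 um outside the candidate's parent tube;
#   segments in `strict_ids`: contact even slightly below the parent wall
#            (midpoint excess > -2 um) is dangerous. Used for the second
#            daughter of a bifurcation against segments the first daughter
#            already touches: two daughters contacting the same third
#            branch would enclose a tunnel (a skeleton loop).
# Returns list(gap, contacts): the worst dangerous surface gap in um
# (+Inf when nothing dangerous approaches within `clearance`) and the ids
# of segments with any near-surface contact.
candidate_clearance <- function(tree, cand_pts, cand_r, parent_id, attach_pt,
                                r_loc, sibling_ids = integer(),
                                clearance = 3, strict_ids = integer(),
                                scale = 1) {
  seg <- tree$segments
  pidx <- match(parent_id, seg$segment_id)
  ppts <- seg$points[[pidx]]
  prad <- seg$radii[[pidx]] * scale
  cand_r <- cand_r * scale
  r_loc <- r_loc * scale
  # signed excess of points over the parent tube surface (> 0 = outside)
  tube_excess <- function(P) {
    d2 <- outer(rowSums(P^2), rowSums(ppts^2), `+`) - 2 * P %*% t(ppts)
    apply(sweep(sqrt(pmax(d2, 0)), 2, prad, `-`), 1, min)
  }
  ball <- 1.5 * (r_loc + cand_r[1]) + clearance
  d_att_c <- sqrt(rowSums(sweep(cand_pts, 2, attach_pt, `-`)^2))
  best <- Inf
  contacts <- integer()
  for (i in seq_len(nrow(seg))) {
    id <- seg$segment_id[i]
    pts <- seg$points[[i]]
    r <- seg$radii[[i]] * scale
    is_parent <- !is.na(parent_id) && id == parent_id
    cu <- if (is_parent) which(d_att_c > ball) else seq_len(nrow(cand_pts))
    if (length(cu) == 0) next
    cp <- cand_pts[cu, , drop = FALSE]
    d2 <- outer(rowSums(cp^2), rowSums(pts^2), `+`) - 2 * cp %*% t(pts)
    gap <- sqrt(pmax(d2, 0)) - outer(cand_r[cu], r, `+`)
    viol <- which(gap < clearance, arr.ind = TRUE)
    if (nrow(viol) == 0) next
    for (k in seq_len(nrow(viol))) {
      a <- viol[k, 1]; b <- viol[k, 2]
      if (is_parent) {
        best <- min(best, gap[a, b])
        next
      }
      ca <- cp[a, ]; eb <- pts[b, ]
      mid <- ca + (eb - ca) * cand_r[cu[a]] / (cand_r[cu[a]] + r[b])
      if (id %in% sibling_ids &&
          sqrt(sum((mid - attach_pt)^2)) <= ball) next
      md2 <- rowSums(sweep(ppts, 2, mid, `-`)^2)
      excess <- min(sqrt(md2) - prad)
      # register only true surface contact near or beyond the parent wall
      if (excess > -2 && gap[a, b] < 2) contacts <- union(contacts, id)
      thr <- if (id %in% strict_ids) -2 else 1
      if (excess > thr) best <- min(best, gap[a, b])
    }
  }
  list(gap = best, contacts = contacts)
}

next_segment_id <- function(tree) {
  if (nrow(tree$segments) == 0) 1L else max(tree$segments$segment_id) + 1L
}

add_segment <- function(tree, parent_id, attach_frac, label, generation,
                        pts, radii, is_terminal = TRUE) {
  row <- tibble(
    segment_id = next_segment_id(tree),
    parent_id = parent_id,
    label = label,
    generation = as.integer(generation),
    is_terminal = is_terminal,
    attach_frac = attach_frac,
    points = list(pts),
    radii = list(radii)
  )
  tree$segments <- dplyr::bind_rows(tree$segments, row)
  tree
}

runif1 <- function(range) runif(1, range[1], range[2])

# jittered attachment fractions with minimum physical separation between
# consecutive attachments (min_sep_um) and from the distal end (end_sep_um)
spaced_fracs <- function(len_um, bases, jitter, min_sep_um, end_sep_um) {
  for (k in 1:30) {
    fr <- bases + runif(length(bases), -jitter, jitter)
    gaps <- diff(c(0, fr, 1)) * len_um
    if (all(gaps[-c(1, length(gaps))] >= min_sep_um) &&
        tail(gaps, 1) >= end_sep_um) {
      return(fr)
    }
  }
  bases
}

#' Build the canonical E12.5 airway tree
#'
#' Constructs the stereotyped topology of the embryonic mouse airway at the
#' start of culture: the trachea (Tr) bifurcates into right (R) and left
#' (L) primary bronchi; R carries the caudal (RCd), accessory (RAc),
#' medial (RMd) and cranial (RCr) secondary branches, and L carries five
#' secondary bronchi (L1-L5). RCd/RAc (and L1-L3) attach laterally along
#' their parent in proximal-to-distal order; RMd/RCr (and L4/L5) form the
#' dichotomous bifurcation at the parent's distal end, with the cranial
#' (higher +y direction) daughter named last (RCr, L5). Segment lengths,
#' radii and branch angles are drawn deterministically from the seed within
#' the ranges in `config$geometry`; self-intersection between non-adjacent
#' segments is prevented by rejection sampling of branch directions.
#'
#' The finished tree is certified to rasterize to a single handle-free
#' solid (Euler characteristic 1 after cavity filling); on the rare seeds
#' whose draws cannot be placed or fail certification, the construction is
#' replayed with a derived sub-seed, so every seed yields a valid tree
#' deterministically.
#'
#' @param config a [growth_config()].
#' @return an `airway_tree` at t = 0 with 12 segments and 9 terminal
#'   branches.
#' @export
build_canonical_tree <- function(config = growth_config()) {
  validate_growth_config(config)
  for (attempt in 0:11) {
    seed_k <- derive_seed(config$rng_seed, 1L + 977L * attempt)
    tree <- try(build_canonical_once(config, seed_k), silent = TRUE)
    if (inherits(tree, "try-error")) next
    # certify across the analysis resolutions: voxel bridging of
    # near-contacts is resolution dependent
    if (tree_genus_ok(tree, 3) && tree_genus_ok(tree, 2.5) &&
        tree_genus_ok(tree, 2)) {
      return(tree)
    }
  }
  stop("could not build a valid canonical tree for this seed")
}

build_canonical_once <- function(config, seed_k) {
  geo <- config$geometry
  withr::with_seed(seed_k, {
    tree <- empty_airway_tree()

    # trachea: origin, caudal (-y)
    d_tr <- c(0, -1, 0)
    L_tr <- runif1(geo$trachea_length)
    pts <- make_polyline(c(0, 0, 0), d_tr, L_tr, geo$sample_step)
    tree <- add_segment(tree, NA_integer_, NA_real_, "Tr", 0,
                        pts, make_radii(nrow(pts), geo$trachea_radius, 0.92),
                        is_terminal = FALSE)
    tr_end <- pts[nrow(pts), ]

    # primary bronchi: with trachea direction (0,-1,0) the perpendicular
    # basis is u = (0,0,-1), v = (1,0,0), so azimuth 270 tilts toward -x
    # (right) and azimuth 90 toward +x (left)
    for (side in c("R", "L")) {
      az <- (if (side == "R") 270 else 90) + runif(1, -15, 15)
      dir <- tilt_direction(d_tr, runif1(geo$primary_angle), az)
      L_p <- runif1(geo$primary_length)
      pts_p <- make_polyline(tr_end, dir, L_p, geo$sample_step)
      tree <- add_segment(tree, 1L, 1.0, side, 1,
                          pts_p, make_radii(nrow(pts_p), geo$primary_radius, 0.9),
                          is_terminal = FALSE)
    }
    r_id <- tree$segments$segment_id[tree$segments$label == "R"]
    l_id <- tree$segments$segment_id[tree$segments$label == "L"]

    # lateral secondaries, proximal to distal; azimuths stratified around
    # the parent so successive bronchi emerge on different flanks, and
    # attachment points spaced so neighbouring junction blobs (radius
    # ~ the secondary radius) stay resolvable in the skeleton
    az_r <- runif(1, 0, 360)
    az_l <- runif(1, 0, 360)
    len_r <- polyline_arclength(segment_row(tree, r_id)$points[[1]])
    len_l <- polyline_arclength(segment_row(tree, l_id)$points[[1]])
    fr_r <- spaced_fracs(len_r, c(0.30, 0.56), 0.05, 60, 88)
    fr_l <- spaced_fracs(len_l, c(0.23, 0.45, 0.66), 0.04, 58, 85)
    tree <- attach_lateral(tree, r_id, fr_r[1], "RCd", geo,
                           az_range = az_r + c(-35, 35))
    tree <- attach_lateral(tree, r_id, fr_r[2], "RAc", geo,
                           az_range = az_r + 150 + c(-35, 35))
    tree <- attach_lateral(tree, l_id, fr_l[1], "L1", geo,
                           az_range = az_l + c(-35, 35))
    tree <- attach_lateral(tree, l_id, fr_l[2], "L2", geo,
                           az_range = az_l + 120 + c(-35, 35))
    tree <- attach_lateral(tree, l_id, fr_l[3], "L3", geo,
                           az_range = az_l + 240 + c(-35, 35))

    # terminal bifurcations; cranial daughter (larger +y direction) is
    # named last in the canonical sequence (RCr, L5)
    tree <- attach_terminal_pair(tree, r_id, c("RMd", "RCr"), geo)
    tree <- attach_terminal_pair(tree, l_id, c("L4", "L5"), geo)

    tree$time_h <- 0
    tree$pressure_Pa <- config$pressure_Pa
    tree$seed <- config$rng_seed
    validate_airway_tree(tree)
    tree
  })
}

# lateral (domain) secondary branch with rejection sampling of direction
attach_lateral <- function(tree, parent_id, frac, label, geo,
                           angle = NULL, length = NULL, radius = NULL,
                           generation = NULL, az_range = c(0, 360),
                           scale = 1, max_try = 50) {
  prow <- segment_row(tree, parent_id)
  ppts <- prow$points[[1]]
  pdir <- ppts[nrow(ppts), ] - ppts[1, ]
  attach_pt <- polyline_point_at(ppts, frac)
  angle <- angle %||% geo$lateral_angle
  length <- length %||% runif1(geo$secondary_length)
  radius <- radius %||% geo$secondary_radius
  generation <- generation %||% (prow$generation + 1L)
  r_loc <- profile_value_at(ppts, prow$radii[[1]], frac)
  for (k in seq_len(max_try)) {
    dir <- tilt_direction(pdir, runif1(angle), runif1(az_range))
    pts <- make_polyline(attach_pt, dir, length, geo$sample_step)
    r <- make_radii(nrow(pts), radius, geo$taper)
    cc <- candidate_clearance(tree, pts, r, parent_id, attach_pt, r_loc,
                              clearance = geo$clearance, scale = scale)
    if (cc$gap > geo$clearance) {
      return(add_segment(tree, parent_id, frac, label, generation, pts, r))
    }
  }
  stop("could not place branch '", label,
       "' without self-intersection after ", max_try, " retries")
}

# dichotomous bifurcation at the parent's distal end; labels[2] goes to the
# daughter whose initial direction has the larger +y (cranial) component
attach_terminal_pair <- function(tree, parent_id, labels, geo,
                                 length = NULL, radius = NULL,
                                 generation = NULL, scale = 1,
                                 max_try = 140) {
  prow <- segment_row(tree, parent_id)
  ppts <- prow$points[[1]]
  pdir <- ppts[nrow(ppts), ] - ppts[1, ]
  attach_pt <- ppts[nrow(ppts), ]
  length <- length %||% runif1(geo$secondary_length)
  radius <- radius %||% geo$secondary_radius
  generation <- generation %||% (prow$generation + 1L)
  for (k in seq_len(max_try)) {
    az1 <- runif(1, 0, 360)
    az2 <- az1 + 180 + runif(1, -30, 30)
    d1 <- tilt_direction(pdir, runif1(geo$terminal_angle), az1)
    d2 <- tilt_direction(pdir, runif1(geo$terminal_angle), az2)
    # the daughters are ordered by their cranial (y) direction downstream;
    # demand a clear separation so the ordering survives skeleton-level
    # direction estimates
    if (abs(d1[2] - d2[2]) < 0.25) next
    len1 <- length * runif(1, 0.92, 1.08)
    len2 <- length * runif(1, 0.92, 1.08)
    p1 <- make_polyline(attach_pt, d1, len1, geo$sample_step)
    p2 <- make_polyline(attach_pt, d2, len2, geo$sample_step)
    r1 <- make_radii(nrow(p1), radius, geo$taper)
    r2 <- make_radii(nrow(p2), radius, geo$taper)
    r_loc <- tail(prow$radii[[1]], 1)
    cc1 <- candidate_clearance(tree, p1, r1, parent_id, attach_pt, r_loc,
                               clearance = geo$clearance, scale = scale)
    if (cc1$gap <= geo$clearance) next
    tree_tmp <- add_segment(tree, parent_id, 1.0, ".tmp", generation, p1, r1)
    tmp_id <- max(tree_tmp$segments$segment_id)
    # the second daughter must not touch anything the first one touches:
    # two daughters contacting the same third branch enclose a tunnel
    cc2 <- candidate_clearance(tree_tmp, p2, r2, parent_id, attach_pt, r_loc,
                               sibling_ids = tmp_id,
                               clearance = geo$clearance,
                               strict_ids = cc1$contacts, scale = scale)
    if (cc2$gap <= geo$clearance) next
    # order daughters: cranial-most direction gets the last label
    if (d1[2] <= d2[2]) {
      lab1 <- labels[1]; lab2 <- labels[2]
    } else {
      lab1 <- labels[2]; lab2 <- labels[1]
    }
    tree_tmp$segments$label[tree_tmp$segments$segment_id == tmp_id] <- lab1
    tree <- add_segment(tree_tmp, parent_id, 1.0, lab2, generation, p2, r2)
    tree$segments$is_terminal[tree$segments$segment_id == parent_id] <- FALSE
    return(tree)
  }
  stop("could not place bifurcation '", paste(labels, collapse = "/"),
       "' without self-intersection after ", max_try, " retries")
}
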