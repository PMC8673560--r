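#' Grow an airway tree under a pressure/time condition
#'
#' Starting from a t = 0 tree (normally [build_canonical_tree()] with the
#' same seed), adds terminal branches one at a time until the deterministic
#' target count `round(9 * fold_area^(a* f(P)))` is reached, where
#' `fold_area = 1 + rate * t` is the pressure-independent linear area
#' schedule, `a*` the configured allometric exponent and `f(P)` the
#' relative branching intensity. Each addition targets a seeded choice of
#' terminal branch and is either lateral (domain branching; the parent
#' keeps its tip) or a dichotomous bifurcation of the tip, 50/50 by a
#' seeded draw. Branch directions are rejection-sampled against
#' self-intersection, with collision tests run at the anticipated final
#' radius scale (growth is performed twice: a first pass learns the
#' area-normalization factor, the second places branches with collisions
#' evaluated at those radii).
#'
#' After growth, pressure-dependent shape changes are applied: the RCr
#' branch and its descendants are narrowed by the `rcr_radius_schedule`
#' fraction, and terminal bud tips are widened by the `cystic_tip_factor`.
#' Finally all radii except RCr's are rescaled by a single factor so that
#' the closed-form basal surface area equals the linear-in-time,
#' pressure-independent target exactly. The finished tree is certified to
#' rasterize to a single handle-free solid (Euler characteristic 1 after
#' cavity filling); if certification fails the seeded growth is replayed
#' with a derived sub-seed.
#'
#' Growth-phase geometry (directions, attachment points, collision tests)
#' is computed on pressure-independent base geometry, so trees grown from
#' the same seed at different pressures share their branching geometry and
#' differ only in branch number and in the scheduled radius changes.
#'
#' @param tree the t = 0 `airway_tree` for this seed.
#' @param config a [growth_config()]; `config$time_h` is the culture time.
#' @return a grown `airway_tree` with `time_h` and `pressure_Pa` set.
#' @export
grow_tree <- function(tree, config) {
  validate_airway_tree(tree)
  validate_growth_config(config)
  t <- config$time_h
  if (t == 0) return(tree)
  geo <- config$geometry

  rfrac <- config$rcr_radius_schedule(config$pressure_Pa, t)
  if (!is.finite(rfrac) || rfrac <= 0) {
    stop("rcr_radius_schedule would produce non-positive radii")
  }

  area0 <- analytic_surface_area(tree)
  target_area <- area0 * (1 + config$baseline_area_growth_rate * t)
  n_target <- target_terminal_count(config, sum(tree$segments$is_terminal))

  grow_once <- function(seed_k, gs) {
    grown <- withr::with_seed(seed_k, {
      g <- elongate_tree(tree, 1 + config$segment_elongation_rate * t)
      add_branches(g, n_target, geo, growth_scale = gs)
    })
    grown <- apply_rcr_schedule(grown, rfrac, geo)
    grown <- apply_cystic_tips(grown,
                               config$cystic_tip_factor(config$pressure_Pa),
                               geo, gs)
    # isometric schedule: rescale radii (RCr excluded) so the closed-form
    # area hits the linear pressure-independent target exactly; the area
    # functional is monotone only in the physical scaling range (junction
    # corrections grow quadratically), so bracket adaptively
    f <- function(s) {
      analytic_surface_area(scale_tree_radii(grown, s, exclude_labels = "RCr")) -
        target_area
    }
    grid <- c(0.2, 0.4, 0.7, 1, 1.3, 1.7, 2.2, 2.8, 3.5)
    fv <- vapply(grid, f, numeric(1))
    k <- which(fv[-length(fv)] * fv[-1] <= 0)
    if (length(k) == 0) {
      stop("could not normalize surface area to the growth schedule")
    }
    s <- uniroot(f, grid[c(k[1], k[1] + 1)], tol = 1e-10)$root
    out <- scale_tree_radii(grown, s, exclude_labels = "RCr")
    rmin <- min(vapply(out$segments$radii, min, numeric(1)))
    if (rmin <= 0) stop("growth schedules produced non-positive radii")
    out$segments$radii <- lapply(out$segments$radii, pmax,
                                 geo$radius_floor %||% 6.5)
    list(tree = out, s = s)
  }

  final <- NULL
  for (attempt in 0:9) {
    seed_k <- derive_seed(config$rng_seed, 2L + 977L * attempt)
    p1 <- try(grow_once(seed_k, 1), silent = TRUE)
    if (inherits(p1, "try-error")) next
    p2 <- try(grow_once(seed_k, p1$s), silent = TRUE)
    if (inherits(p2, "try-error")) next
    # coarse screen first, then certify across the analysis resolutions
    # (voxel bridging of near-contacts is resolution dependent)
    spacings <- sort(geo$certify_spacings %||% c(3.5, 3, 2.5, 2),
                     decreasing = TRUE)
    ok <- TRUE
    for (sp in spacings) {
      if (!tree_genus_ok(p2$tree, sp)) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      final <- p2$tree
      break
    }
  }
  if (is.null(final)) {
    stop("could not generate a loop-free grown tree for this configuration")
  }

  final$time_h <- t
  final$pressure_Pa <- config$pressure_Pa
  final$seed <- config$rng_seed
  validate_airway_tree(final)
  final
}

# rescale every polyline about its own start by factor e, re-anchoring each
# child at its attachment fraction of the (rescaled) parent
elongate_tree <- function(tree, e) {
  seg <- tree$segments
  order_idx <- order(seg$generation, seg$segment_id)
  new_pts <- seg$points
  for (i in order_idx) {
    pts <- seg$points[[i]]
    if (is.na(seg$parent_id[i])) {
      start <- pts[1, ]
    } else {
      pidx <- match(seg$parent_id[i], seg$segment_id)
      start <- polyline_point_at(new_pts[[pidx]], seg$attach_frac[i])
    }
    new_pts[[i]] <- sweep((pts - matrix(pts[1, ], nrow(pts), 3, byrow = TRUE)) * e,
                          2, start, `+`)
  }
  tree$segments$points <- new_pts
  tree
}

# sequential seeded branch additions up to the target terminal count
add_branches <- function(tree, n_target, geo, growth_scale = 1) {
  guard <- 0
  while (sum(tree$segments$is_terminal) < n_target) {
    guard <- guard + 1
    if (guard > 10 * n_target) stop("branch addition did not converge")
    terminals <- sort(tree$segments$segment_id[tree$segments$is_terminal])
    placed <- FALSE
    for (attempt in seq_len(min(10, length(terminals)))) {
      target <- terminals[sample.int(length(terminals), 1)]
      res <- try(add_one_branch(tree, target, geo, growth_scale), silent = TRUE)
      if (!inherits(res, "try-error")) {
        tree <- res
        placed <- TRUE
        break
      }
      terminals <- setdiff(terminals, target)
      if (length(terminals) == 0) break
    }
    if (!placed) {
      stop("could not place a new branch without self-intersection ",
           "(all candidate targets exhausted)")
    }
  }
  tree
}

add_one_branch <- function(tree, target, geo, growth_scale = 1) {
  trow <- segment_row(tree, target)
  kids <- tree$segments[!is.na(tree$segments$parent_id) &
                          tree$segments$parent_id == target, ]
  last_frac <- if (nrow(kids) == 0) 0 else max(kids$attach_frac)
  # space lateral attachments in physical units so neighbouring junction
  # blobs (which scale with the final radii) stay separated
  len_seg <- polyline_arclength(trow$points[[1]])
  r_end <- tail(trow$radii[[1]], 1)
  min_sep_um <- 1.2 * (1 + geo$child_radius_factor) * r_end * growth_scale
  lo <- max(0.55, last_frac + min_sep_um / max(len_seg, 1))
  # the parent tip beyond the last lateral must still protrude further
  # than the junction blob, or the skeleton cannot tell it from a spur
  hi <- 1 - (1.6 * r_end * growth_scale + 20) / max(len_seg, 1)
  hi <- min(0.88, hi)
  lateral_ok <- lo < hi
  lateral <- lateral_ok && runif(1) < 0.5
  gen <- trow$generation + 1L
  len <- runif1(geo$new_branch_length) *
    geo$child_length_factor^max(0, gen - 3)
  # a bud must protrude well beyond the parent junction blob, or the
  # skeleton cannot resolve it from a thinning artifact
  len <- max(len, 40, 1.5 * r_end * growth_scale + 25)
  k <- nrow(kids)

  if (lateral) {
    frac <- runif(1, lo, hi)
    r_loc <- profile_value_at(trow$points[[1]], trow$radii[[1]], frac)
    radius <- min(max(r_loc * geo$child_radius_factor, geo$min_radius), r_loc)
    res <- try(
      attach_lateral(tree, target, frac, paste0(trow$label, ".", k + 1), geo,
                     angle = geo$new_branch_angle, length = len,
                     radius = radius, generation = gen,
                     scale = growth_scale),
      silent = TRUE)
    if (!inherits(res, "try-error")) return(res)
    # crowded flank: fall back to splitting the tip instead
    r_end <- tail(trow$radii[[1]], 1)
    radius <- min(max(r_end * geo$child_radius_factor, geo$min_radius), r_end)
    attach_terminal_pair(tree, target,
                         paste0(trow$label, ".", k + 1:2), geo,
                         length = len, radius = radius, generation = gen,
                         scale = growth_scale)
  } else {
    r_end <- tail(trow$radii[[1]], 1)
    radius <- min(max(r_end * geo$child_radius_factor, geo$min_radius), r_end)
    attach_terminal_pair(tree, target,
                         paste0(trow$label, ".", k + 1:2), geo,
                         length = len, radius = radius, generation = gen,
                         scale = growth_scale)
  }
}

# narrow the RCr branch and its descendants by the schedule fraction
apply_rcr_schedule <- function(tree, rfrac, geo) {
  seg <- tree$segments
  rcr_id <- seg$segment_id[seg$label == "RCr"]
  if (length(rcr_id) != 1) return(tree)
  in_lobe <- rep(FALSE, nrow(seg))
  in_lobe[match(rcr_id, seg$segment_id)] <- TRUE
  repeat {
    more <- !in_lobe & !is.na(seg$parent_id) &
      seg$parent_id %in% seg$segment_id[in_lobe]
    if (!any(more)) break
    in_lobe <- in_lobe | more
  }
  tree$segments$radii[in_lobe] <- lapply(seg$radii[in_lobe], `*`, rfrac)
  tree
}

# Widen the distal 40 percent of terminal branches toward the tip. The
# widening is collision-aware: a cystic bud expands only into available
# space, so the factor is backed off per branch until the widened tip
# keeps clear of non-adjacent tubes (evaluated at the anticipated final
# radius scale `gs`), which keeps the solid handle-free.
apply_cystic_tips <- function(tree, factor, geo = NULL, gs = 1) {
  if (abs(factor - 1) < 1e-12) return(tree)
  clearance <- if (is.null(geo)) 5 else geo$clearance
  seg <- tree$segments
  for (i in order(seg$segment_id[seg$is_terminal])) {
    idx <- which(seg$is_terminal)[i]
    pts <- seg$points[[idx]]
    s <- cumulative_arclength(pts)
    fr <- if (s[length(s)] > 0) s / s[length(s)] else rep(0, nrow(pts))
    ramp <- pmax(0, (fr - 0.6) / 0.4)
    pid <- seg$parent_id[idx]
    f_i <- factor
    repeat {
      radii <- seg$radii[[idx]] * (1 + (f_i - 1) * ramp)
      if (is.na(pid) || f_i <= 1.02) break
      prow <- segment_row(tree, pid)
      attach_pt <- polyline_point_at(prow$points[[1]], seg$attach_frac[idx])
      r_loc <- profile_value_at(prow$points[[1]], prow$radii[[1]],
                                seg$attach_frac[idx])
      twins <- seg$segment_id[!is.na(seg$parent_id) & seg$parent_id == pid &
                                seg$attach_frac >= 1 - 1e-6 &
                                seg$segment_id != seg$segment_id[idx]]
      rest <- tree
      rest$segments <- seg[-idx, ]
      cc <- candidate_clearance(rest, pts, radii, pid, attach_pt, r_loc,
                                sibling_ids = twins, clearance = clearance,
                                scale = gs)
      if (cc$gap > 5) break  # above the voxel-bridging scale
      f_i <- 1 + (f_i - 1) * 0.8
    }
    tree$segments$radii[[idx]] <- radii
  }
  tree
}
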