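# Closed-form (oracle) morphometry of an airway tree.
#
# Segments are unions of tapered capsules: frustum side walls plus
# hemispherical caps at both polyline ends. Junction overlap is corrected
# approximately: for each attachment the child's buried stub (a tube of
# length ~ the local parent radius, plus its proximal cap) and the hole it
# cuts in the parent surface are subtracted. The correction is second
# order; voxel-based measurements agree within the documented tolerances.

segment_lateral_area <- function(pts, r) {
  dp <- pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE]
  len <- sqrt(rowSums(dp^2))
  dr <- diff(r)
  slant <- sqrt(len^2 + dr^2)
  sum(pi * (r[-length(r)] + r[-1]) * slant)
}

segment_frustum_volume <- function(pts, r) {
  dp <- pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE]
  len <- sqrt(rowSums(dp^2))
  r1 <- r[-length(r)]
  r2 <- r[-1]
  sum(pi / 3 * len * (r1^2 + r1 * r2 + r2^2))
}

# per-attachment overlap corrections (area, volume)
attachment_correction <- function(tree, i) {
  seg <- tree$segments
  pid <- seg$parent_id[i]
  prow <- segment_row(tree, pid)
  ppts <- prow$points[[1]]
  pr <- prow$radii[[1]]
  frac <- seg$attach_frac[i]
  R_loc <- profile_value_at(ppts, pr, frac)
  cpts <- seg$points[[i]]
  r_c <- seg$radii[[i]][1]
  cdir <- cpts[min(3, nrow(cpts)), ] - cpts[1, ]
  pdir <- ppts[nrow(ppts), ] - ppts[1, ]
  sinth <- sin(angle_between_deg(cdir, pdir) * pi / 180)
  sinth <- max(sinth, 0.5)
  if (frac >= 1 - 1e-6) {
    lb <- R_loc
    obliq <- 1
  } else {
    lb <- min(R_loc / sinth, 2 * R_loc)
    obliq <- min(1 / sinth, 2)
  }
  # fibres of a fat daughter (r_c comparable to R_loc) exit the parent at
  # different depths; the mean exit chord across the cross-section is the
  # average of sqrt(1 - u^2) over the tube width
  rho <- min(1, r_c / R_loc)
  chord <- if (rho < 1e-6) 1 else
    (rho * sqrt(1 - rho^2) + asin(rho)) / (2 * rho)
  area <- 2 * pi * r_c * lb * chord + 2 * pi * r_c^2 + pi * r_c^2 * obliq
  vol <- pi * r_c^2 * lb * chord + 2 / 3 * pi * r_c^3
  c(area = area, vol = vol)
}

#' Closed-form surface area of an airway tree
#'
#' @param tree an `airway_tree`.
#' @return basal surface area in square micrometres.
#' @export
analytic_surface_area <- function(tree) {
  seg <- tree$segments
  if (nrow(seg) == 0) return(0)
  area <- 0
  for (i in seq_len(nrow(seg))) {
    pts <- seg$points[[i]]
    r <- seg$radii[[i]]
    area <- area + segment_lateral_area(pts, r) +
      2 * pi * r[1]^2 + 2 * pi * r[length(r)]^2
  }
  for (i in which(!is.na(seg$parent_id))) {
    area <- area - attachment_correction(tree, i)[["area"]]
  }
  area
}

#' Closed-form volume of an airway tree
#'
#' @param tree an `airway_tree`.
#' @return lumen-inclusive volume in cubic micrometres.
#' @export
analytic_volume <- function(tree) {
  seg <- tree$segments
  if (nrow(seg) == 0) return(0)
  vol <- 0
  for (i in seq_len(nrow(seg))) {
    pts <- seg$points[[i]]
    r <- seg$radii[[i]]
    vol <- vol + segment_frustum_volume(pts, r) +
      2 / 3 * pi * r[1]^3 + 2 / 3 * pi * r[length(r)]^3
  }
  for (i in which(!is.na(seg$parent_id))) {
    vol <- vol - attachment_correction(tree, i)[["vol"]]
  }
  vol
}

# uniform radius scaling, optionally excluding segments (by label)
scale_tree_radii <- function(tree, scale, exclude_labels = character()) {
  keep <- !(tree$segments$label %in% exclude_labels)
  tree$segments$radii[keep] <- lapply(tree$segments$radii[keep], `*`, scale)
  tree
}

#' Oracle morphometric record of an airway tree
#'
#' Ground-truth metrics computed in closed form from the tree geometry:
#' terminal branch count, basal surface area, lumen-inclusive volume, and
#' the mean neck radius of each canonically labelled branch (mean of the
#' radius profile over the arclength window, default 10-60 percent from
#' the proximal end, the window used for the RCr readout).
#'
#' @param tree an `airway_tree`.
#' @param window neck arclength-fraction window for per-label radii.
#' @return a one-row tibble (a `MorphometricRecord`): time_h, pressure_Pa,
#'   terminal_branch_count, surface_area_um2, volume_um3, and a
#'   `branch_radii` list column holding a named vector of label radii.
#' @export
analytic_metrics <- function(tree, window = c(0.1, 0.6)) {
  seg <- tree$segments
  labs <- seg$label[!is.na(seg$label) & !startsWith(seg$label, ".")]
  radii <- vapply(labs, function(lb) {
    i <- match(lb, seg$label)
    profile_window_mean(seg$points[[i]], seg$radii[[i]], window)
  }, numeric(1))
  tibble(
    time_h = tree$time_h,
    pressure_Pa = tree$pressure_Pa,
    terminal_branch_count = sum(seg$is_terminal),
    surface_area_um2 = analytic_surface_area(tree),
    volume_um3 = analytic_volume(tree),
    branch_radii = list(radii)
  )
}
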