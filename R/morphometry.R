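#' Basal epithelial surface area of a binary volume
#'
#' Measures the area of the outer surface of the epithelium+lumen solid.
#' The binary mask is smoothed with a small Gaussian (default sigma = 1
#' voxel, which suppresses the staircase bias of voxelized surfaces) and the
#' area is computed by the co-area formula, the integral of the gradient
#' magnitude of the smoothed indicator over the volume -- in the continuum
#' this equals the area of the 0.5-level isosurface.
#'
#' @param volume a [labeled_volume()].
#' @param sigma_vox Gaussian smoothing in voxels before the gradient.
#' @return surface area in square micrometres; 0 (with a warning) for an
#'   empty volume.
#' @export
surface_area <- function(volume, sigma_vox = 1) {
  stopifnot(inherits(volume, "labeled_volume"))
  if (.count_foreground_cpp(volume$mask) == 0) {
    warning("empty volume: surface area is 0")
    return(0)
  }
  .surface_area_cpp(volume$mask, dim(volume$mask), volume$spacing_um,
                    sigma_vox)
}

#' Lumen-inclusive volume of a binary volume
#'
#' Foreground voxel count times the physical voxel volume.
#'
#' @param volume a [labeled_volume()].
#' @return volume in cubic micrometres.
#' @export
region_volume <- function(volume) {
  stopifnot(inherits(volume, "labeled_volume"))
  .count_foreground_cpp(volume$mask) * prod(volume$spacing_um)
}

#' Annotate morphometric records with fold-changes relative to a baseline
#'
#' Fold-increases are computed relative to the explant immediately after
#' dissection (the t = 0 record), matching how whole-lung metrics are
#' normalized in explant culture studies.
#'
#' @param records tibble of morphometric records with a `record_id` column
#'   and the extensive metrics `surface_area_um2`, `volume_um3`,
#'   `terminal_branch_count`.
#' @param baseline_id the `record_id` of the baseline record.
#' @return the records with `fold_area`, `fold_branches`, `fold_volume`
#'   columns added; the baseline row has fold-changes of exactly 1.
#' @export
fold_change_series <- function(records, baseline_id) {
  i <- match(baseline_id, records$record_id)
  if (is.na(i)) stop("baseline record '", baseline_id, "' not found")
  base <- records[i, ]
  for (col in c("surface_area_um2", "volume_um3", "terminal_branch_count")) {
    if (!is.na(base[[col]]) && base[[col]] <= 0) {
      stop("baseline ", col, " must be > 0")
    }
  }
  records$fold_area <- records$surface_area_um2 / base$surface_area_um2
  records$fold_branches <- records$terminal_branch_count /
    base$terminal_branch_count
  records$fold_volume <- records$volume_um3 / base$volume_um3
  records
}

#' Measure a volume through the full image pipeline
#'
#' Runs skeletonization, spur pruning, lineage assignment and whole-lung
#' morphometry on one binary volume and returns a one-row morphometric
#' record plus the intermediate objects.
#'
#' @param volume a [labeled_volume()].
#' @param root_hint passed to [assign_lineage()].
#' @param window neck window for per-label branch radii.
#' @return list with `record` (one-row tibble), `skeleton` (pruned
#'   `skeleton_graph`) and `assignment` (`lineage_assignment`).
#' @export
measure_volume <- function(volume, root_hint = "topmost",
                           window = c(0.1, 0.6)) {
  skel <- prune_spurs(skeletonize(volume))
  assignment <- assign_lineage(skel, root_hint)
  labs <- assignment$branches$label
  labs <- labs[!is.na(labs)]
  radii <- vapply(labs, function(lb) {
    branch_radius(skel, assignment, lb, window)
  }, numeric(1))
  record <- tibble(
    terminal_branch_count = count_terminal_branches(skel, assignment),
    surface_area_um2 = surface_area(volume),
    volume_um3 = region_volume(volume),
    branch_radii = list(radii)
  )
  list(record = record, skeleton = skel, assignment = assignment)
}
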