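#' Binary labelled volume
#'
#' The pipeline's image representation: a 3D binary voxel grid (raw
#' storage, 0/1) with physical voxel spacing and origin in micrometres.
#' The voxel centre of array index (i, j, k) sits at
#' `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param mask a raw, logical, or numeric 3D array (non-zero = foreground).
#' @param spacing_um voxel spacing, length-1 or length-3, micrometres (> 0).
#' @param origin_um physical position of voxel (1, 1, 1), micrometres.
#' @return an object of class `labeled_volume`.
#' @export
labeled_volume <- function(mask, spacing_um, origin_um = c(0, 0, 0)) {
  if (length(spacing_um) == 1) spacing_um <- rep(spacing_um, 3)
  if (any(spacing_um <= 0)) stop("spacing components must be > 0")
  d <- dim(mask)
  if (is.null(d) || length(d) != 3) stop("mask must be a 3D array")
  if (!is.raw(mask)) {
    mask <- as.raw(ifelse(as.logical(mask), 1L, 0L))
    dim(mask) <- d
  }
  structure(list(mask = mask, spacing_um = as.numeric(spacing_um),
                 origin_um = as.numeric(origin_um)),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$mask)
  cat("<labeled_volume>\n")
  cat(sprintf("  dims: %d x %d x %d, spacing: %s um\n",
              d[1], d[2], d[3], paste(format(x$spacing_um), collapse = " x ")))
  cat(sprintf("  foreground voxels: %.0f\n", .count_foreground_cpp(x$mask)))
  invisible(x)
}

#' Rasterize an airway tree into a binary volume
#'
#' The foreground is the union of tapered capsules: spheres of linearly
#' interpolated radius swept along each segment polyline, which rounds
#' every branch tip with a hemispherical cap. Rasterization of a connected
#' tree yields a single 26-connected component; the result is
#' deterministic.
#'
#' @param tree an `airway_tree`.
#' @param spacing_um voxel spacing in micrometres (scalar or length 3).
#'   The smallest tube radius must be at least 2 voxels at this spacing.
#' @param margin_um padding added around the tree bounding box.
#' @return a [labeled_volume()].
#' @export
rasterize <- function(tree, spacing_um = 2, margin_um = NULL,
                      check_radius = TRUE) {
  if (length(spacing_um) == 1) spacing_um <- rep(spacing_um, 3)
  if (any(spacing_um <= 0)) stop("spacing components must be > 0")
  seg <- tree$segments
  if (nrow(seg) == 0) {
    m <- array(raw(1), dim = c(8, 8, 8))
    return(labeled_volume(m, spacing_um))
  }
  rmin <- min(vapply(seg$radii, min, numeric(1)))
  if (check_radius && rmin < 2 * max(spacing_um)) {
    stop(sprintf(
      "minimum tube radius (%.2f um) is below 2 voxels at spacing %.2f um; use a finer spacing",
      rmin, max(spacing_um)))
  }
  pieces <- do.call(rbind, lapply(seq_len(nrow(seg)), function(i) {
    pts <- seg$points[[i]]
    r <- seg$radii[[i]]
    m <- nrow(pts)
    cbind(pts[-m, , drop = FALSE], r[-m], pts[-1, , drop = FALSE], r[-1])
  }))
  allpts <- do.call(rbind, seg$points)
  rmax <- max(vapply(seg$radii, max, numeric(1)))
  margin <- margin_um %||% (rmax + 4 * max(spacing_um))
  lo <- apply(allpts, 2, min) - margin
  hi <- apply(allpts, 2, max) + margin
  dims <- as.integer(ceiling((hi - lo) / spacing_um)) + 1L
  mask <- .rasterize_cpp(pieces, dims, spacing_um, lo)
  dim(mask) <- dims
  labeled_volume(mask, spacing_um, lo)
}

# Certify that a tree rasterizes to a single handle-free solid: fill
# cavities, require one face-connected component and Euler characteristic
# 1 (chi = 1 - handles for a connected solid without cavities).
tree_genus_report <- function(tree, spacing_um = 2.5) {
  v <- rasterize(tree, spacing_um, check_radius = FALSE)
  d <- dim(v$mask)
  m <- .fill_cavities_cpp(v$mask, d)
  dim(m) <- d
  list(ncomp = .count_components_cpp(m, d, 6L),
       chi = .euler_characteristic_cpp(m, d))
}

tree_genus_ok <- function(tree, spacing_um = 2.5) {
  # fast path: chi == 1 on the raw mask certifies a connected solid with
  # no handles and no cavities; only on failure fill cavities and recount
  v <- rasterize(tree, spacing_um, check_radius = FALSE)
  d <- dim(v$mask)
  chi <- .euler_characteristic_cpp(v$mask, d)
  if (abs(chi - 1) < 0.5) return(TRUE)
  m <- .fill_cavities_cpp(v$mask, d)
  dim(m) <- d
  .count_components_cpp(m, d, 6L) == 1 &&
    abs(.euler_characteristic_cpp(m, d) - 1) < 0.5
}

#' Number of connected foreground components
#'
#' @param volume a `labeled_volume`.
#' @param connectivity 26 (default) or 6.
#' @return integer component count.
#' @export
n_components <- function(volume, connectivity = 26) {
  .count_components_cpp(volume$mask, dim(volume$mask), as.integer(connectivity))
}
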