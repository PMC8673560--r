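# Readers/writers for the standard interchange formats: SWC skeletons
# (one sample per line: id type x y z radius parent), multi-page TIFF
# volumes with a JSON sidecar for voxel spacing, and CSV branch tables.

#' Write a skeleton or airway tree to SWC
#'
#' One point per centerline sample (id, type, x, y, z, radius, parent;
#' type 0, parent -1 at roots). For skeletons the radius field is the
#' distance-transform radius. A JSON sidecar (`<path>.json`) maps subtree
#' root ids to lineage labels when an assignment/labelled tree is given.
#'
#' @param x a `skeleton_graph` or `airway_tree`.
#' @param path output file path.
#' @param assignment optional [assign_lineage()] result (skeleton input).
#' @return the path, invisibly.
#' @export
write_swc <- function(x, path, assignment = NULL) {
  if (inherits(x, "skeleton_graph")) {
    rows <- swc_rows_skeleton(x)
    labels <- if (!is.null(assignment)) {
      br <- assignment$branches
      ok <- !is.na(br$label)
      setNames(
        vapply(which(ok), function(i) br$segment_ids[[i]][1], integer(1)),
        br$label[ok]
      )
    } else {
      NULL
    }
    sidecar <- list(format = "skeleton",
                    spacing_um = x$spacing_um,
                    label_to_segment = as.list(labels))
  } else if (inherits(x, "airway_tree")) {
    rows <- swc_rows_tree(x)
    seg <- x$segments
    sidecar <- list(format = "airway_tree",
                    label_to_segment = setNames(as.list(seg$segment_id),
                                                seg$label))
  } else {
    stop("write_swc handles skeleton_graph or airway_tree objects")
  }
  writeLines(c("# SWC centerline export",
               "# id type x y z radius parent",
               sprintf("%d %d %.4f %.4f %.4f %.4f %d",
                       rows$id, rows$type, rows$x, rows$y, rows$z,
                       rows$radius, rows$parent)),
             path)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

# SWC rows for a skeleton: spanning-tree parents over the point graph
swc_rows_skeleton <- function(skel) {
  n <- nrow(skel$points)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(skel$edges) > 0) g <- igraph::add_edges(g, t(skel$edges))
  comp <- igraph::components(g)$membership
  parent <- rep(-1L, n)
  for (cl in sort(unique(comp))) {
    vs <- which(comp == cl)
    root <- vs[order(-skel$points$y[vs], vs)][1]
    bfs <- igraph::bfs(g, root = root, father = TRUE,
                       unreachable = FALSE)
    fa <- as.integer(bfs$father)
    reach <- which(!is.na(fa) | seq_len(n) == root)
    parent[setdiff(reach, root)] <- fa[setdiff(reach, root)]
  }
  tibble(id = seq_len(n), type = 0L,
         x = skel$points$x, y = skel$points$y, z = skel$points$z,
         radius = skel$points$radius, parent = parent)
}

# SWC rows for a ground-truth tree: polylines sampled as-is
swc_rows_tree <- function(tree) {
  seg <- tree$segments
  rows <- list()
  first_id <- integer(nrow(seg))
  next_id <- 1L
  for (i in seq_len(nrow(seg))) {
    pts <- seg$points[[i]]
    r <- seg$radii[[i]]
    m <- nrow(pts)
    ids <- next_id:(next_id + m - 1L)
    first_id[i] <- ids[1]
    parent <- c(NA_integer_, ids[-m])
    rows[[i]] <- tibble(id = ids, type = 0L,
                        x = pts[, 1], y = pts[, 2], z = pts[, 3],
                        radius = r, parent = parent, seg_index = i)
    next_id <- next_id + m
  }
  out <- dplyr::bind_rows(rows)
  # link each segment's first sample to the nearest sample of its parent
  for (i in seq_len(nrow(seg))) {
    pid <- seg$parent_id[i]
    j <- which(out$seg_index == i)[1]
    if (is.na(pid)) {
      out$parent[j] <- -1L
      next
    }
    pi_rows <- which(out$seg_index == match(pid, seg$segment_id))
    d <- (out$x[pi_rows] - out$x[j])^2 + (out$y[pi_rows] - out$y[j])^2 +
      (out$z[pi_rows] - out$z[j])^2
    out$parent[j] <- out$id[pi_rows[which.min(d)]]
  }
  out$seg_index <- NULL
  out
}

#' Read an SWC file into a skeleton graph
#'
#' @param path SWC file path.
#' @return a `skeleton_graph` rebuilt from the sample points and parent
#'   links.
#' @export
read_swc <- function(path) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z",
                                         "radius", "parent"))
  idx <- match(tab$parent, tab$id)
  has_parent <- !is.na(idx)
  edges <- cbind(which(has_parent), idx[has_parent])
  points <- tibble(point_id = seq_len(nrow(tab)),
                   x = tab$x, y = tab$y, z = tab$z, radius = tab$radius)
  skeleton_graph_core(points, edges)
}

#' Write a binary volume as a multi-page TIFF
#'
#' One z-slice per page, 8-bit, foreground 255. Voxel spacing and origin
#' are recorded in a JSON sidecar (`<path>.json`).
#'
#' @param volume a [labeled_volume()].
#' @param path output TIFF path.
#' @return the path, invisibly.
#' @export
write_volume_tiff <- function(volume, path) {
  d <- dim(volume$mask)
  pages <- lapply(seq_len(d[3]), function(k) {
    m <- matrix(as.numeric(volume$mask[, , k] != 0), d[1], d[2])
    t(m)  # TIFF rows = y
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  jsonlite::write_json(list(spacing_um = volume$spacing_um,
                            origin_um = volume$origin_um,
                            dims = d),
                       paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF volume
#'
#' @param path TIFF path; if `<path>.json` exists, spacing and origin are
#'   taken from it.
#' @param spacing_um fallback voxel spacing when no sidecar is present.
#' @return a [labeled_volume()].
#' @export
read_volume_tiff <- function(path, spacing_um = 2) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nz <- length(pages)
  ny <- nrow(pages[[1]])
  nx <- ncol(pages[[1]])
  mask <- array(raw(1), dim = c(nx, ny, nz))
  for (k in seq_len(nz)) {
    mask[, , k] <- as.raw(ifelse(t(pages[[k]]) > 0.5, 1L, 0L))
  }
  origin <- c(0, 0, 0)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    spacing_um <- meta$spacing_um
    origin <- meta$origin_um
  }
  labeled_volume(mask, spacing_um, origin)
}

#' Per-branch CSV table of a labelled skeleton
#'
#' @param skel a `skeleton_graph`.
#' @param assignment an [assign_lineage()] result.
#' @param path optional CSV output path.
#' @return tibble with label, parent label, attachment position, length,
#'   mean neck radius and terminal flag.
#' @export
export_branch_table <- function(skel, assignment, path = NULL) {
  br <- assignment$branches
  kind <- setNames(skel$nodes$kind, skel$nodes$node_id)
  ori <- orient_skeleton(skel)
  segs <- ori$segments
  terminal <- vapply(seq_len(nrow(br)), function(i) {
    last_seg <- tail(br$segment_ids[[i]], 1)
    j <- match(last_seg, segs$segment_id)
    kind[[as.character(segs$distal_node[j])]] == "endpoint"
  }, logical(1))
  tab <- tibble(
    label = br$label,
    parent = br$label[match(br$parent_branch, br$branch_id)],
    attach_um = br$attach_s,
    length_um = br$length_um,
    mean_radius_um = vapply(seq_len(nrow(br)), function(i) {
      profile_window_mean(br$pts[[i]], br$radii[[i]], c(0.1, 0.6))
    }, numeric(1)),
    terminal = terminal
  )
  if (!is.null(path)) write.csv(tab, path, row.names = FALSE)
  tab
}
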