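#' Ground-truth airway tree
#'
#' An `airway_tree` is a rooted tree of tapered tube segments. Each segment
#' carries a polyline (>= 2 points, micrometres), a per-point radius
#' profile, a lineage label from the canonical murine vocabulary
#' (Tr, R, L, RCd, RAc, RMd, RCr, L1-L5, plus generated descendant labels
#' such as "RCr.1"), a generation index, and a terminal flag. Children
#' attach to their parent at an arclength fraction `attach_frac`
#' (1 = at the parent's distal end, i.e. a dichotomous bifurcation;
#' < 1 = lateral/domain branching).
#'
#' @param segments tibble with columns segment_id, parent_id, label,
#'   generation, is_terminal, attach_frac, points (list of m x 3 matrices),
#'   radii (list of numeric vectors).
#' @param time_h,pressure_Pa,seed condition metadata carried on the tree.
#' @return an object of class `airway_tree`.
#' @keywords internal
new_airway_tree <- function(segments, time_h = 0, pressure_Pa = NA_real_,
                            seed = NA_integer_) {
  structure(list(
    segments = segments,
    time_h = time_h,
    pressure_Pa = pressure_Pa,
    seed = seed
  ), class = "airway_tree")
}

#' An airway tree with no segments
#'
#' Used as the degenerate input for rasterization and metric edge cases.
#' @return an `airway_tree` with zero segments.
#' @export
empty_airway_tree <- function() {
  new_airway_tree(tibble(
    segment_id = integer(), parent_id = integer(), label = character(),
    generation = integer(), is_terminal = logical(), attach_frac = double(),
    points = list(), radii = list()
  ))
}

#' @export
print.airway_tree <- function(x, ...) {
  cat("<airway_tree>\n")
  cat(sprintf("  %d segments, %d terminal branches\n",
              nrow(x$segments), sum(x$segments$is_terminal)))
  cat(sprintf("  time: %g h, pressure: %s Pa, seed: %s\n",
              x$time_h,
              format(x$pressure_Pa), format(x$seed)))
  invisible(x)
}

#' Validate airway-tree invariants
#'
#' Checks that the segment table forms a rooted tree (single root labelled
#' Tr with exactly two children when the canonical topology is present),
#' that all radii are positive, and that each radius profile matches its
#' polyline length.
#'
#' @param tree an `airway_tree`.
#' @return the tree, invisibly; errors on violation.
#' @export
validate_airway_tree <- function(tree) {
  seg <- tree$segments
  if (nrow(seg) == 0) return(invisible(tree))
  if (anyDuplicated(seg$segment_id)) stop("duplicate segment ids")
  roots <- which(is.na(seg$parent_id))
  if (length(roots) != 1) stop("tree must have exactly one root segment")
  if (!all(seg$parent_id[-roots] %in% seg$segment_id)) {
    stop("dangling parent references")
  }
  for (i in seq_len(nrow(seg))) {
    pts <- seg$points[[i]]
    r <- seg$radii[[i]]
    if (nrow(pts) < 2) stop("polyline must have >= 2 points")
    if (length(r) != nrow(pts)) stop("radius profile length must equal polyline length")
    if (any(r <= 0)) stop("all radii must be > 0")
  }
  # acyclicity: walking parents from every segment must reach the root
  parent <- setNames(seg$parent_id, seg$segment_id)
  for (id in seg$segment_id) {
    seen <- integer()
    cur <- id
    while (!is.na(parent[[as.character(cur)]])) {
      if (cur %in% seen) stop("cycle detected in segment parentage")
      seen <- c(seen, cur)
      cur <- parent[[as.character(cur)]]
    }
  }
  if ("Tr" %in% seg$label) {
    if (sum(seg$label == "Tr") != 1) stop("exactly one segment may be labelled Tr")
    tr_id <- seg$segment_id[seg$label == "Tr"]
    if (!is.na(seg$parent_id[seg$segment_id == tr_id])) stop("Tr must be the root segment")
    nch <- sum(seg$parent_id == tr_id, na.rm = TRUE)
    if (nch != 2) stop("Tr must have exactly two children (R, L)")
  }
  invisible(tree)
}

# children ids of a segment, ordered by (attach_frac, creation order)
segment_children <- function(tree, id) {
  seg <- tree$segments
  kids <- seg[!is.na(seg$parent_id) & seg$parent_id == id, ]
  kids$segment_id[order(kids$attach_frac, kids$segment_id)]
}

segment_row <- function(tree, id) {
  tree$segments[match(id, tree$segments$segment_id), ]
}

#' Node table of an airway tree
#'
#' Derived view: one node per segment endpoint and per attachment point.
#' @param tree an `airway_tree`.
#' @return tibble with node id, segment_id, kind, and position (um).
#' @export
tree_nodes <- function(tree) {
  seg <- tree$segments
  out <- lapply(seq_len(nrow(seg)), function(i) {
    pts <- seg$points[[i]]
    tibble(
      segment_id = seg$segment_id[i],
      kind = c("proximal", "distal"),
      x = c(pts[1, 1], pts[nrow(pts), 1]),
      y = c(pts[1, 2], pts[nrow(pts), 2]),
      z = c(pts[1, 3], pts[nrow(pts), 3])
    )
  })
  out <- dplyr::bind_rows(out)
  out$node_id <- seq_len(nrow(out))
  out
}

# expected skeleton-level topology of a tree: junction count, endpoint
# count, and maximal junction-free segment (run) count. Interior
# attachments split the parent into additional runs.
tree_skeleton_topology <- function(tree) {
  seg <- tree$segments
  if (nrow(seg) == 0) {
    return(list(n_junction = 0L, n_endpoint = 0L, n_run = 0L, n_terminal = 0L))
  }
  eps <- 1e-6
  interior <- sum(seg$attach_frac < 1 - eps, na.rm = TRUE)
  # end-attachments grouped per (parent, ~frac 1) junction
  end_attach <- seg[!is.na(seg$parent_id) & seg$attach_frac >= 1 - eps, ]
  end_junctions <- length(unique(end_attach$parent_id))
  n_junction <- interior + end_junctions
  n_terminal <- sum(seg$is_terminal)
  n_endpoint <- n_terminal + 1L  # terminals plus the root (trachea) end
  n_run <- nrow(seg) + interior
  list(n_junction = as.integer(n_junction),
       n_endpoint = as.integer(n_endpoint),
       n_run = as.integer(n_run),
       n_terminal = as.integer(n_terminal))
}
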