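# Branch lineage annotation: assign the canonical murine airway names
# (Tr, R, L, RCd/RAc/RMd/RCr, L1-L5, dotted descendant labels) to a
# skeleton, following the published naming scheme for the E12.5 tree.

CANONICAL_R <- c("RCd", "RAc", "RMd", "RCr")
CANONICAL_L <- c("L1", "L2", "L3", "L4", "L5")

# locate the root node: nearest endpoint to a position hint, or the
# topmost endpoint (maximum y; the trachea sits at the top of the image)
find_root_node <- function(skel, root_hint = "topmost") {
  eps <- skel$nodes[skel$nodes$kind == "endpoint", ]
  if (nrow(eps) == 0) stop("skeleton has no endpoints")
  if (is.numeric(root_hint) && length(root_hint) == 3) {
    d <- (eps$x - root_hint[1])^2 + (eps$y - root_hint[2])^2 +
      (eps$z - root_hint[3])^2
    return(eps$node_id[order(d, eps$node_id)][1])
  }
  eps$node_id[order(-eps$y, eps$node_id)][1]
}

# orient all segments away from the root: per segment, proximal/distal
# node and graph depth
orient_skeleton <- function(skel, root_hint = "topmost") {
  segs <- skel$segments
  root <- find_root_node(skel, root_hint)
  nid <- skel$nodes$node_id
  g <- igraph::make_empty_graph(length(nid), directed = FALSE)
  vmap <- match(c(segs$node1, segs$node2), nid)
  e <- cbind(vmap[seq_len(nrow(segs))], vmap[nrow(segs) + seq_len(nrow(segs))])
  g <- igraph::add_edges(g, t(e))
  dist <- igraph::distances(g, v = match(root, nid))[1, ]
  prox <- ifelse(dist[match(segs$node1, nid)] <= dist[match(segs$node2, nid)],
                 segs$node1, segs$node2)
  segs$proximal_node <- prox
  segs$distal_node <- ifelse(prox == segs$node1, segs$node2, segs$node1)
  list(segments = segs, root_node = root)
}

# polyline and radii of a segment oriented proximal -> distal
oriented_profile <- function(skel, seg_row) {
  prof <- segment_profile(skel, seg_row$segment_id)
  if (seg_row$proximal_node != seg_row$node1) {
    prof$pts <- prof$pts[rev(seq_len(nrow(prof$pts))), , drop = FALSE]
    prof$radii <- rev(prof$radii)
  }
  prof
}

# mean direction over [skip, skip + span] um of arclength: directions are
# measured beyond the junction blob (skip ~ the junction radius), where
# the centerline has settled onto the branch axis
initial_direction <- function(pts, span = 30, skip = 0) {
  s <- cumulative_arclength(pts)
  L <- s[length(s)]
  if (skip >= L * 0.8) skip <- 0.2 * L
  a <- polyline_point_at(pts, min(1, skip / L))
  b <- polyline_point_at(pts, min(1, (skip + span) / L))
  if (sum((b - a)^2) == 0) b <- pts[nrow(pts), ]
  unit3(b - a)
}

#' Assign canonical lineage labels to a skeleton
#'
#' Identifies the root (trachea) endpoint -- by default the topmost
#' endpoint, matching images with the trachea at the top -- and walks the
#' skeleton assembling anatomical branches: at each junction, an outgoing
#' segment that continues within 30 degrees of the incoming direction
#' extends the current branch (a lateral/domain junction), otherwise all
#' outgoing segments start daughter branches (a dichotomous bifurcation).
#' The root branch is the trachea (Tr); its two daughters are named R and
#' L by the sign of their initial x-displacement; R's daughters receive
#' RCd, RAc, RMd, RCr and L's daughters L1-L5 in proximal-to-distal
#' attachment order (daughters of the terminal bifurcation are ordered
#' with the cranial-most, largest +y direction, last); deeper daughters of
#' a branch labelled X are X.1, X.2, ... in the same ordering.
#'
#' @param skel a `skeleton_graph` (a tree).
#' @param root_hint "topmost" or a position (length-3, um).
#' @return a `lineage_assignment`: tibble of branches with labels, a
#'   segment_id -> label map, the root segment id, and any unassigned
#'   branches (with a warning when canonical names run out).
#' @export
assign_lineage <- function(skel, root_hint = "topmost") {
  ori <- orient_skeleton(skel, root_hint)
  segs <- ori$segments
  root_segs <- which(segs$proximal_node == ori$root_node)
  if (length(root_segs) != 1) stop("root endpoint must start exactly one segment")

  # assemble branches (chains of runs glued at pass-through junctions)
  branches <- list()
  make_branch <- function(start_idx, parent_branch, attach_s) {
    runs <- integer()
    pts <- NULL
    radii <- NULL
    idx <- start_idx
    repeat {
      runs <- c(runs, segs$segment_id[idx])
      prof <- oriented_profile(skel, segs[idx, ])
      if (is.null(pts)) {
        pts <- prof$pts
        radii <- prof$radii
      } else {
        pts <- rbind(pts, prof$pts[-1, , drop = FALSE])
        radii <- c(radii, prof$radii[-1])
      }
      nd <- segs$distal_node[idx]
      outgoing <- which(segs$proximal_node == nd &
                          segs$segment_id != segs$segment_id[idx])
      if (length(outgoing) == 0) break
      # measure directions outside the junction blob
      r_j <- skel$nodes$radius[match(nd, skel$nodes$node_id)]
      s_in <- cumulative_arclength(pts)
      L_in <- s_in[length(s_in)]
      a <- polyline_point_at(pts, max(0, (L_in - r_j - 30) / L_in))
      b <- polyline_point_at(pts, max(0, min(1, (L_in - r_j) / L_in)))
      inc_dir <- if (sum((b - a)^2) > 0) unit3(b - a) else
        unit3(pts[nrow(pts), ] - pts[1, ])
      angs <- vapply(outgoing, function(j) {
        p <- oriented_profile(skel, segs[j, ])
        angle_between_deg(inc_dir, initial_direction(p$pts, skip = r_j))
      }, numeric(1))
      aligned <- which(angs < 30)
      if (length(outgoing) == 1 && length(aligned) == 1) {
        idx <- outgoing[aligned]
        next
      }
      if (length(aligned) == 1 && length(outgoing) >= 2) {
        # lateral junction: one continuation, the rest are daughters
        s_here <- polyline_arclength(pts)
        for (j in setdiff(outgoing, outgoing[aligned])) {
          enqueue(j, s_here)
        }
        idx <- outgoing[aligned]
        next
      }
      # dichotomous bifurcation (or ambiguous): all outgoing are daughters
      s_here <- polyline_arclength(pts)
      for (j in outgoing) enqueue(j, s_here)
      break
    }
    tibble(
      parent_branch = parent_branch,
      attach_s = attach_s,
      segment_ids = list(runs),
      length_um = polyline_arclength(pts),
      ydir = initial_direction(pts, skip = radii[1])[2],
      xdisp = initial_direction(pts, span = 40, skip = radii[1])[1],
      pts = list(pts),
      radii = list(radii)
    )
  }

  queue <- list()
  enqueue <- function(seg_idx, attach_s) {
    queue[[length(queue) + 1]] <<- list(idx = seg_idx,
                                        parent = current_branch_id,
                                        attach_s = attach_s)
  }
  current_branch_id <- 1L
  branches[[1]] <- make_branch(root_segs, NA_integer_, NA_real_)
  next_id <- 2L
  qi <- 1
  while (qi <= length(queue)) {
    item <- queue[[qi]]
    qi <- qi + 1
    current_branch_id <- next_id
    branches[[next_id]] <- make_branch(item$idx, item$parent, item$attach_s)
    next_id <- next_id + 1L
  }
  br <- dplyr::bind_rows(branches)
  br$branch_id <- seq_len(nrow(br))

  # order daughters of each branch by (attachment position, then cranial
  # direction last) and assign labels
  br$label <- NA_character_
  br$label[1] <- "Tr"
  daughters_of <- function(bid) {
    kids <- which(!is.na(br$parent_branch) & br$parent_branch == bid)
    kids[order(br$attach_s[kids], br$ydir[kids], kids)]
  }
  tr_kids <- daughters_of(1L)
  if (length(tr_kids) != 2) {
    stop("trachea has ", length(tr_kids),
         " daughters; cannot disambiguate R and L primary bronchi")
  }
  r_first <- br$xdisp[tr_kids[1]] < br$xdisp[tr_kids[2]]
  br$label[tr_kids[if (r_first) 1 else 2]] <- "R"
  br$label[tr_kids[if (r_first) 2 else 1]] <- "L"

  unassigned <- integer()
  assign_children <- function(bid) {
    kids <- daughters_of(bid)
    if (length(kids) == 0) return(invisible())
    lab <- br$label[bid]
    names_pool <- if (is.na(lab)) {
      rep(NA_character_, length(kids))
    } else if (lab == "R") {
      CANONICAL_R
    } else if (lab == "L") {
      CANONICAL_L
    } else {
      paste0(lab, ".", seq_along(kids))
    }
    for (k in seq_along(kids)) {
      if (k <= length(names_pool) && !is.na(names_pool[k])) {
        br$label[kids[k]] <<- names_pool[k]
      } else {
        unassigned <<- c(unassigned, kids[k])
      }
    }
    if (length(kids) > length(names_pool)) {
      warning("branch '", lab, "' has ", length(kids),
              " daughters but only ", length(names_pool),
              " canonical names; extras left unassigned")
    }
    for (k in kids) assign_children(k)
  }
  assign_children(tr_kids[1])
  assign_children(tr_kids[2])

  seg_labels <- setNames(rep(NA_character_, nrow(segs)),
                         as.character(segs$segment_id))
  for (i in seq_len(nrow(br))) {
    seg_labels[as.character(br$segment_ids[[i]])] <- br$label[i]
  }

  structure(list(
    branches = br[, c("branch_id", "label", "parent_branch", "attach_s",
                      "length_um", "segment_ids", "pts", "radii")],
    segment_labels = seg_labels,
    root_segment_id = segs$segment_id[root_segs],
    root_node = ori$root_node,
    unassigned = unassigned
  ), class = "lineage_assignment")
}

#' @export
print.lineage_assignment <- function(x, ...) {
  cat("<lineage_assignment>\n")
  labs <- x$branches$label
  cat(sprintf("  %d branches; labelled: %s\n", nrow(x$branches),
              paste(labs[!is.na(labs)], collapse = ", ")))
  if (length(x$unassigned)) {
    cat(sprintf("  %d unassigned\n", length(x$unassigned)))
  }
  invisible(x)
}

#' Count terminal branches of a skeleton
#'
#' A terminal branch is a segment whose distal end (away from the root) is
#' an endpoint -- a distal bud tip. The trachea is excluded even when
#' degenerate (when a lineage assignment labelling it is supplied).
#'
#' @param skel a pruned `skeleton_graph`.
#' @param assignment optional [assign_lineage()] result; used to exclude
#'   the trachea.
#' @param root_hint passed to the orientation step.
#' @return integer count of terminal branches.
#' @export
count_terminal_branches <- function(skel, assignment = NULL,
                                    root_hint = "topmost") {
  ori <- orient_skeleton(skel, root_hint)
  segs <- ori$segments
  kind <- setNames(skel$nodes$kind, skel$nodes$node_id)
  terminal <- vapply(seq_len(nrow(segs)), function(i) {
    kind[[as.character(segs$distal_node[i])]] == "endpoint"
  }, logical(1))
  if (!is.null(assignment)) {
    tr <- assignment$branches$segment_ids[[
      which(assignment$branches$label == "Tr")[1]]]
    terminal <- terminal & !(segs$segment_id %in% tr)
  }
  sum(terminal)
}

#' Neck radius of a named branch
#'
#' Mean skeleton radius over an arclength window of the labelled branch,
#' measured from its proximal junction. The default window (10 to 60
#' percent) targets the branch neck while avoiding the junction blob and
#' the (possibly cystic) tip.
#'
#' @param skel a `skeleton_graph`.
#' @param assignment an [assign_lineage()] result for this skeleton.
#' @param label canonical branch label (default "RCr", the right cranial
#'   branch).
#' @param window arclength-fraction window.
#' @return mean neck radius in micrometres.
#' @export
branch_radius <- function(skel, assignment, label = "RCr",
                          window = c(0.1, 0.6)) {
  i <- which(assignment$branches$label == label)
  if (length(i) != 1) stop("label '", label, "' is not assigned")
  pts <- assignment$branches$pts[[i]]
  radii <- assignment$branches$radii[[i]]
  profile_window_mean(pts, radii, window)
}
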