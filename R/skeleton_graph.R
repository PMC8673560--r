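# SkeletonGraph: centerline points with radii, organised into nodes
# (junctions = degree >= 3 voxel clusters, endpoints = degree <= 1) and
# segments (maximal junction-free paths).

# Build the structured graph from a point table and an edge list.
# points: tibble(point_id, x, y, z, radius) positions in um.
# A junction-junction run shorter than the two junction-blob radii lies
# entirely inside one anatomical junction; such runs (a thinning artifact
# of fat junction blobs) are absorbed into a single junction cluster.
skeleton_graph_core <- function(points, edges, spacing_um = NA, origin_um = NA) {
  forced <- integer()
  for (it in 1:50) {
    skel <- skeleton_graph_build(points, edges, spacing_um, origin_um, forced)
    segs <- skel$segments
    if (nrow(segs) == 0) return(skel)
    kind <- setNames(skel$nodes$kind, skel$nodes$node_id)
    nrad <- setNames(skel$nodes$radius, skel$nodes$node_id)
    jj <- vapply(seq_len(nrow(segs)), function(i) {
      kind[[as.character(segs$node1[i])]] == "junction" &&
        kind[[as.character(segs$node2[i])]] == "junction" &&
        segs$length_um[i] < 1.0 * max(nrad[[as.character(segs$node1[i])]],
                                    nrad[[as.character(segs$node2[i])]])
    }, logical(1))
    if (!any(jj)) return(skel)
    forced <- union(forced, unlist(segs$point_ids[jj]))
  }
  skel
}

skeleton_graph_build <- function(points, edges, spacing_um = NA,
                                 origin_um = NA, forced = integer()) {
  n <- nrow(points)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  deg <- igraph::degree(g)

  jun <- sort(union(which(deg >= 3), forced[deg[forced] >= 2]))
  # junction clusters: connected components of the junction-voxel subgraph
  nodes <- list()
  node_of_point <- rep(NA_integer_, n)
  nid <- 0L
  if (length(jun) > 0) {
    sg <- igraph::induced_subgraph(g, jun)
    comp <- igraph::components(sg)$membership
    for (cl in sort(unique(comp))) {
      nid <- nid + 1L
      ids <- jun[comp == cl]
      node_of_point[ids] <- nid
      nodes[[nid]] <- tibble(
        node_id = nid, kind = "junction",
        x = mean(points$x[ids]), y = mean(points$y[ids]),
        z = mean(points$z[ids]),
        radius = max(points$radius[ids]),
        point_ids = list(sort(ids))
      )
    }
  }
  for (ep in which(deg <= 1)) {
    nid <- nid + 1L
    node_of_point[ep] <- nid
    nodes[[nid]] <- tibble(
      node_id = nid, kind = "endpoint",
      x = points$x[ep], y = points$y[ep], z = points$z[ep],
      radius = points$radius[ep], point_ids = list(ep)
    )
  }
  nodes <- if (length(nodes)) dplyr::bind_rows(nodes) else
    tibble(node_id = integer(), kind = character(), x = double(),
           y = double(), z = double(), radius = double(), point_ids = list())

  # runs: components of the graph with junction voxels removed
  run_idx <- setdiff(seq_len(n), jun)
  segs <- list()
  sid <- 0L
  if (length(run_idx) > 0) {
    sg <- igraph::induced_subgraph(g, run_idx)
    comp <- igraph::components(sg)$membership
    adj <- igraph::as_adj_list(g)
    for (cl in sort(unique(comp))) {
      ids <- run_idx[comp == cl]
      ord <- order_path(sg, which(comp == cl))
      ids <- run_idx[ord]
      m <- length(ids)
      # junction clusters adjacent to the run ends
      end_nodes <- function(pid) {
        nb <- as.integer(adj[[pid]])
        unique(node_of_point[nb[nb %in% jun]])
      }
      j1 <- end_nodes(ids[1])
      j2 <- end_nodes(ids[m])
      if (m == 1) {
        own <- node_of_point[ids[1]]  # endpoint node when deg <= 1
        if (length(j1) >= 2) {
          node1 <- j1[1]; node2 <- j1[2]
        } else if (length(j1) == 1) {
          node1 <- j1[1]
          node2 <- if (!is.na(own)) own else j1[1]
        } else {
          node1 <- own; node2 <- own
        }
      } else {
        node1 <- if (length(j1) >= 1) j1[1] else node_of_point[ids[1]]
        node2 <- if (length(j2) >= 1) j2[length(j2)] else node_of_point[ids[m]]
      }
      sid <- sid + 1L
      segs[[sid]] <- tibble(segment_id = sid, node1 = node1, node2 = node2,
                            point_ids = list(ids))
    }
  }
  segs <- if (length(segs)) dplyr::bind_rows(segs) else
    tibble(segment_id = integer(), node1 = integer(), node2 = integer(),
           point_ids = list())

  skel <- structure(list(points = points, edges = edges, nodes = nodes,
                         segments = segs, spacing_um = spacing_um,
                         origin_um = origin_um),
                    class = "skeleton_graph")
  # per-segment geometry summaries
  if (nrow(segs) > 0) {
    prof <- lapply(segs$segment_id, function(id) segment_profile(skel, id))
    skel$segments$length_um <- vapply(prof, function(p) polyline_arclength(p$pts),
                                      numeric(1))
    skel$segments$mean_radius_um <- vapply(prof, function(p) mean(p$radii),
                                           numeric(1))
    skel$segments$n_points <- vapply(segs$point_ids, length, integer(1))
  }
  skel
}

# order the vertices of a path component of sg (vertex ids local to sg)
order_path <- function(sg, vids) {
  if (length(vids) == 1) return(vids)
  sub <- igraph::induced_subgraph(sg, vids)
  d <- igraph::degree(sub)
  if (any(d > 2)) stop("skeleton run is not a simple path")
  start <- which(d <= 1)
  start <- start[which.min(vids[start])]
  ord <- as.integer(igraph::dfs(sub, root = start)$order)
  vids[ord]
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat("<skeleton_graph>\n")
  cat(sprintf("  %d points, %d segments, %d junctions, %d endpoints\n",
              nrow(x$points), nrow(x$segments),
              sum(x$nodes$kind == "junction"),
              sum(x$nodes$kind == "endpoint")))
  invisible(x)
}

node_position <- function(skel, node_id) {
  i <- match(node_id, skel$nodes$node_id)
  c(skel$nodes$x[i], skel$nodes$y[i], skel$nodes$z[i])
}

# full polyline and radius profile of a segment, node1 -> node2, with
# junction-cluster centroids appended at junction ends
segment_profile <- function(skel, segment_id) {
  i <- match(segment_id, skel$segments$segment_id)
  if (is.na(i)) stop("unknown segment_id: ", segment_id)
  ids <- skel$segments$point_ids[[i]]
  pts <- cbind(skel$points$x[ids], skel$points$y[ids], skel$points$z[ids])
  radii <- skel$points$radius[ids]
  for (end in c(1, 2)) {
    nd <- if (end == 1) skel$segments$node1[i] else skel$segments$node2[i]
    ni <- match(nd, skel$nodes$node_id)
    if (!is.na(ni) && skel$nodes$kind[ni] == "junction") {
      row <- c(skel$nodes$x[ni], skel$nodes$y[ni], skel$nodes$z[ni])
      if (end == 1) {
        pts <- rbind(row, pts)
        radii <- c(skel$nodes$radius[ni], radii)
      } else {
        pts <- rbind(pts, row)
        radii <- c(radii, skel$nodes$radius[ni])
      }
    }
  }
  list(pts = unname(pts), radii = unname(radii))
}

# iteratively delete the longest edge of any 26-adjacency triangle; such
# triangles are digitization artifacts of diagonal steps, and removing the
# long diagonal keeps the short path, so connectivity is preserved
# After triangle cleanup, remaining cycles are classified: when the solid
# itself is certified handle-free (Euler characteristic 1), every skeleton
# cycle is a digitization artifact of the 26-connectivity (a tiny square
# of a double-wide ridge, or a diagonal near-contact bridge between
# tubes) and is broken by dropping one edge; if the solid has genuine
# handles, only short (<= 6 edge) cycles are broken and anything larger
# raises an error -- non-tree topology is out of contract.
break_digitization_cycles <- function(edges, n_points, solid_is_tree = FALSE) {
  if (nrow(edges) == 0 || n_points == 0) return(edges)
  repeat {
    g <- igraph::make_empty_graph(n_points, directed = FALSE)
    g <- igraph::add_edges(g, t(edges))
    ncomp <- igraph::components(g)$no
    if (nrow(edges) <= n_points - ncomp) return(edges)
    mst <- igraph::mst(g, weights = rep(1, igraph::ecount(g)))
    extra <- igraph::as_edgelist(igraph::difference(g, mst))
    a <- extra[1, 1]; b <- extra[1, 2]
    path <- igraph::shortest_paths(mst, a, b)$vpath[[1]]
    if (length(path) > 6 && !solid_is_tree) {
      stop("skeleton contains loops after thinning; non-tree topology is out of contract")
    }
    keep <- !((pmin(edges[, 1], edges[, 2]) == min(a, b)) &
                (pmax(edges[, 1], edges[, 2]) == max(a, b)))
    edges <- edges[keep, , drop = FALSE]
  }
}

clean_triangle_edges <- function(coords_um, edges) {
  if (nrow(edges) == 0) return(edges)
  repeat {
    g <- igraph::make_empty_graph(nrow(coords_um), directed = FALSE)
    g <- igraph::add_edges(g, t(edges))
    tri <- igraph::triangles(g)
    if (length(tri) == 0) return(edges)
    v <- sort(as.integer(tri[1:3]))
    cand <- rbind(c(v[1], v[2]), c(v[1], v[3]), c(v[2], v[3]))
    w <- sqrt(rowSums((coords_um[cand[, 1], , drop = FALSE] -
                         coords_um[cand[, 2], , drop = FALSE])^2))
    drop <- cand[which.max(w), ]
    keep <- !((pmin(edges[, 1], edges[, 2]) == min(drop)) &
                (pmax(edges[, 1], edges[, 2]) == max(drop)))
    edges <- edges[keep, , drop = FALSE]
  }
}
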