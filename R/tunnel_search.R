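# ---------------------------------------------------------------------------
# Grid-based curved tunnel search (Caver-style stage-2 screen).
#
# A regular 3D grid is laid over the selected atoms; each node carries the
# clearance r = min_i(|node - a_i| - vdw_i).  Nodes below the cutoff radius
# are blocked; nodes with clearance >= shell_radius are "bulk" (solvent).
# Exit nodes are free non-bulk nodes within shell_depth of bulk (the
# molecular-surface boundary eroded inward).  Tunnels are lowest-cost paths
# from the seed to exit nodes under the throughput cost
# edge_length / r_mid^2, with r_mid the clearance at the edge midpoint,
# grouped into distinct tunnels by pairwise path divergence.
# ---------------------------------------------------------------------------

#' Tunnel-search seed point from a residue pair
#'
#' Midpoint of the Calpha atoms of two residues.
#'
#' @param frame an `ip_frame`.
#' @param topology matching `ip_topology`.
#' @param residue_pair length-2 vector of residue indices.
#' @param chain optional chain restriction.
#' @return length-3 numeric (A).
#' @export
seed_point <- function(frame, topology, residue_pair, chain = NULL) {
  if (length(residue_pair) != 2)
    stop_ip("selection_error", "residue_pair must name two residues")
  rows <- select_calpha(topology, residue_pair, chain)
  colMeans(frame$coords[rows, , drop = FALSE])
}

# clearance field on a regular grid covering the atoms' bounding box
clearance_grid <- function(atom_xyz, atom_vdw, grid_step, margin, r_cap) {
  ax <- lapply(1:3, function(k)
    seq(min(atom_xyz[, k]) - margin, max(atom_xyz[, k]) + margin,
        by = grid_step))
  nd <- vapply(ax, length, integer(1))
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  cl <- pmin(clearance_points(pts, atom_xyz, atom_vdw), r_cap)
  list(axes = ax, dim = nd,
       clearance = array(cl, dim = nd), step = grid_step, r_cap = r_cap)
}

# one 6-neighbour dilation of mask, restricted to cells where allowed is TRUE
dilate_mask <- function(mask, allowed) {
  d <- dim(mask)
  out <- mask
  shift <- function(m, k, by) {
    r <- array(FALSE, dim = d)
    idx_src <- idx_dst <- lapply(d, seq_len)
    if (by == 1L) { idx_dst[[k]] <- 2:d[k]; idx_src[[k]] <- 1:(d[k] - 1) }
    else { idx_dst[[k]] <- 1:(d[k] - 1); idx_src[[k]] <- 2:d[k] }
    r[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    r
  }
  for (k in 1:3) for (by in c(1L, -1L)) out <- out | shift(mask, k, by)
  out & allowed
}

# 13 forward neighbour offsets of the 26-neighbourhood
.neighbour_offsets <- local({
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[!(off[, 1] == 0 & off[, 2] == 0 & off[, 3] == 0), ]
  off[off[, 3] > 0 | (off[, 3] == 0 & (off[, 2] > 0 |
      (off[, 2] == 0 & off[, 1] > 0))), , drop = FALSE]
})

#' Search curved tunnels from an interior seed to the protein surface
#'
#' @param frame an `ip_frame`.
#' @param topology matching `ip_topology`.
#' @param seed length-3 start point (A); must have clearance >=
#'   `cutoff_radius`.
#' @param tm_selection residue indices considered as tunnel-bounding atoms
#'   (default: all protein residues).
#' @param cutoff_radius minimum admissible sphere radius (A), default 1.8.
#' @param shell_radius clearance at which a node counts as bulk solvent (A),
#'   default 6.
#' @param shell_depth inward erosion of the surface layer defining exit
#'   nodes (A), default 3.
#' @param grid_step grid spacing (A), default 0.8.
#' @param cluster_threshold pairwise path divergence separating distinct
#'   tunnels (A), default 4.5.
#' @param r_cap clearance cap (A).
#' @param keep_grid retain the clearance grid in attribute `grid` (for
#'   diagnostics and oracle checks).
#' @return list of tunnels, each a `tunnel` list: `frame_index`, `spheres`
#'   (data.frame `x, y, z, radius`), `length` (A), `bottleneck_radius` (A),
#'   `cost`, `endpoint` (`NA` until [classify_endpoint()]), `n_members`
#'   (paths grouped into this tunnel).  Ordered by increasing cost.
#' @export
search_tunnels <- function(frame, topology, seed, tm_selection = NULL,
                           cutoff_radius = 1.8, shell_radius = 6,
                           shell_depth = 3, grid_step = 0.8,
                           cluster_threshold = 4.5, r_cap = 10,
                           keep_grid = FALSE) {
  rows <- select_atoms(topology, residues = tm_selection,
                       segment = "protein")
  if (!length(rows)) stop_ip("selection_error", "tm_selection matches no atoms")
  axyz <- frame$coords[rows, , drop = FALSE]
  avdw <- topology$atoms$vdw_radius[rows]
  seed_cl <- min(sqrt(rowSums(sweep(axyz, 2, seed)^2)) - avdw)
  if (seed_cl < cutoff_radius)
    stop_ip("seed_buried",
            "seed clearance %.2f A is below the cutoff radius %.2f A",
            seed_cl, cutoff_radius)
  g <- clearance_grid(axyz, avdw, grid_step,
                      margin = shell_radius + 2 * grid_step, r_cap = r_cap)
  free <- g$clearance >= cutoff_radius
  bulk <- g$clearance >= shell_radius
  interior <- free & !bulk
  # exit layer: interior cells within shell_depth of bulk, walking only
  # through admissible cells
  reach <- bulk
  for (s in seq_len(max(1L, ceiling(shell_depth / grid_step))))
    reach <- dilate_mask(reach, free | bulk)
  exit_mask <- interior & reach

  node_id <- array(0L, dim = g$dim)
  node_id[interior] <- seq_len(sum(interior))
  n_nodes <- sum(interior)
  if (n_nodes == 0L) return(empty_tunnel_list(g, keep_grid))
  node_lin <- which(interior)                      # linear index per node
  node_ijk <- arrayInd(node_lin, g$dim)
  node_xyz <- cbind(g$axes[[1]][node_ijk[, 1]],
                    g$axes[[2]][node_ijk[, 2]],
                    g$axes[[3]][node_ijk[, 3]])
  # seed node: nearest interior node
  d2seed <- rowSums(sweep(node_xyz, 2, seed)^2)
  seed_node <- which.min(d2seed)

  # build edges over the 26-neighbourhood
  edges <- build_grid_edges(g, interior, node_id, node_xyz, axyz, avdw,
                            cutoff_radius)
  if (nrow(edges) == 0L) return(empty_tunnel_list(g, keep_grid))
  gr <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n_nodes)))
  igraph::E(gr)$weight <- edges[, 3]

  exit_nodes <- node_id[exit_mask & interior]
  exit_nodes <- setdiff(exit_nodes, seed_node)
  if (!length(exit_nodes)) return(empty_tunnel_list(g, keep_grid))
  dists <- igraph::distances(gr, v = as.character(seed_node),
                             to = as.character(exit_nodes))[1, ]
  reachable <- exit_nodes[is.finite(dists)]
  if (!length(reachable)) return(empty_tunnel_list(g, keep_grid))
  rcosts <- dists[is.finite(dists)]
  # thin the exit set before path extraction: walking exits cheapest-first,
  # drop any exit closer than the clustering threshold to one already kept
  # (the kept exit of each surface patch is its cheapest one)
  ord <- order(rcosts)
  kept <- integer(0)
  for (e in reachable[ord]) {
    if (!length(kept) ||
        min(rowSums(sweep(node_xyz[kept, , drop = FALSE], 2,
                          node_xyz[e, ])^2)) >= cluster_threshold^2)
      kept <- c(kept, e)
  }
  keep_idx <- match(kept, reachable)
  sp <- igraph::shortest_paths(gr, from = as.character(seed_node),
                               to = as.character(kept),
                               output = "vpath")
  paths <- lapply(sp$vpath, function(v) as.integer(igraph::as_ids(v)))
  costs <- unname(rcosts[keep_idx])
  # a tunnel ends at its FIRST surface contact: truncate each path at the
  # first exit-layer node (beyond the seed) and de-duplicate the results,
  # so no tunnel may pass through the exit layer and continue elsewhere
  is_exit <- logical(n_nodes)
  is_exit[node_id[exit_mask & interior]] <- TRUE
  all_dist <- unname(dists)
  dist_of <- function(node) {
    i <- match(node, exit_nodes)
    if (!is.na(i)) all_dist[i] else NA_real_
  }
  for (k in seq_along(paths)) {
    p <- paths[[k]]
    hit <- which(is_exit[p] & seq_along(p) > 1L)
    if (length(hit) && hit[1] < length(p)) {
      paths[[k]] <- p[seq_len(hit[1])]
      d <- dist_of(p[hit[1]])
      if (!is.na(d)) costs[k] <- d
    }
  }
  ends <- vapply(paths, function(p) p[length(p)], integer(1))
  first <- !duplicated(ends)
  paths <- paths[first]
  costs <- costs[first]

  tunnels <- group_paths(paths, costs, node_xyz, g$clearance, node_lin,
                         cluster_threshold, frame$frame_index)
  if (keep_grid) attr(tunnels, "grid") <- c(g, list(interior = interior,
                                                    exit_mask = exit_mask,
                                                    node_xyz = node_xyz,
                                                    node_id = node_id,
                                                    edges = edges,
                                                    seed_node = seed_node))
  tunnels
}

empty_tunnel_list <- function(g, keep_grid) {
  out <- list()
  if (keep_grid) attr(out, "grid") <- g
  out
}

# vectorised edge construction: for each forward offset, pair valid nodes,
# evaluate clearance at edge midpoints, drop edges whose midpoint clearance
# is below the cutoff, cost = length / r_mid^2
build_grid_edges <- function(g, interior, node_id, node_xyz, atom_xyz,
                             atom_vdw, cutoff_radius) {
  d <- g$dim
  from <- integer(0); to <- integer(0); mid <- NULL
  lens <- numeric(0)
  for (r in seq_len(nrow(.neighbour_offsets))) {
    off <- .neighbour_offsets[r, ]
    src_rng <- lapply(1:3, function(k) {
      if (off[k] >= 0) 1:(d[k] - off[k]) else (1 - off[k]):d[k]
    })
    dst_rng <- lapply(1:3, function(k) src_rng[[k]] + off[k])
    a <- interior[src_rng[[1]], src_rng[[2]], src_rng[[3]], drop = FALSE] &
         interior[dst_rng[[1]], dst_rng[[2]], dst_rng[[3]], drop = FALSE]
    if (!any(a)) next
    ids_a <- node_id[src_rng[[1]], src_rng[[2]], src_rng[[3]], drop = FALSE][a]
    ids_b <- node_id[dst_rng[[1]], dst_rng[[2]], dst_rng[[3]], drop = FALSE][a]
    from <- c(from, ids_a); to <- c(to, ids_b)
    lens <- c(lens, rep(sqrt(sum((off * g$step)^2)), length(ids_a)))
  }
  if (!length(from))
    return(matrix(numeric(0), ncol = 3))
  mids <- (node_xyz[from, , drop = FALSE] + node_xyz[to, , drop = FALSE]) / 2
  r_mid <- pmin(clearance_points(mids, atom_xyz, atom_vdw), g$r_cap)
  ok <- r_mid >= cutoff_radius
  cbind(from[ok], to[ok], lens[ok] / r_mid[ok]^2)
}

# symmetrised mean closest-point distance between two polyline point sets
path_divergence <- function(pa, pb) {
  d2 <- pmax(dist2_xyz(pa, pb), 0)
  (mean(sqrt(apply(d2, 1, min))) + mean(sqrt(apply(d2, 2, min)))) / 2
}

# greedy grouping of shortest paths into distinct tunnels: paths are taken
# in order of increasing cost; a path joins the first existing tunnel whose
# representative it diverges from by less than the threshold, else founds a
# new tunnel (the representative stays the cheapest member)
group_paths <- function(paths, costs, node_xyz, clearance, node_lin,
                        threshold, frame_index) {
  ord <- order(costs)
  reps <- list(); rep_cost <- numeric(0); members <- integer(0)
  for (i in ord) {
    pxyz <- node_xyz[paths[[i]], , drop = FALSE]
    placed <- FALSE
    for (k in seq_along(reps)) {
      if (path_divergence(pxyz, reps[[k]]$xyz) < threshold) {
        members[k] <- members[k] + 1L
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps[[length(reps) + 1L]] <- list(xyz = pxyz, nodes = paths[[i]],
                                        cost = costs[i])
      members <- c(members, 1L)
    }
  }
  lapply(seq_along(reps), function(k) {
    nodes <- reps[[k]]$nodes
    xyz <- node_xyz[nodes, , drop = FALSE]
    radii <- clearance[node_lin[nodes]]
    spheres <- data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                          radius = radii)
    structure(list(frame_index = frame_index,
                   spheres = spheres,
                   length = sum(sqrt(rowSums(diff(xyz)^2))),
                   bottleneck_radius = min(radii),
                   cost = reps[[k]]$cost,
                   endpoint = NA_character_,
                   n_members = members[k]),
              class = "tunnel")
  })
}

#' @export
print.tunnel <- function(x, ...) {
  cat(sprintf(
    "tunnel (frame %d): %d spheres, length %.1f A, bottleneck %.2f A, cost %.3f, endpoint %s\n",
    x$frame_index + 1L, nrow(x$spheres), x$length, x$bottleneck_radius,
    x$cost, x$endpoint))
  invisible(x)
}

#' Classify a tunnel endpoint against the membrane slab
#'
#' Intracellular when the final sphere lies below the slab, extracellular
#' when above; endpoints inside the slab are membrane-facing lateral exits
#' and are excluded from intracellular/extracellular pairing.
#'
#' @param tunnel a `tunnel`.
#' @param slab a `membrane_slab`.
#' @return the tunnel with `endpoint` set to one of `"intracellular"`,
#'   `"extracellular"`, `"lateral"`.
#' @export
classify_endpoint <- function(tunnel, slab) {
  if (nrow(tunnel$spheres) < 2)
    stop_ip("input_error", "tunnel needs at least 2 spheres")
  zf <- tunnel$spheres$z[nrow(tunnel$spheres)]
  tunnel$endpoint <- if (zf < slab$z_lower) "intracellular"
  else if (zf > slab$z_upper) "extracellular"
  else "lateral"
  tunnel
}

#' Select frames with simultaneously open intracellular and extracellular routes
#'
#' A frame is an open conformation when it has at least one intracellular
#' and one extracellular tunnel; the selected pair minimises the summed
#' tunnel cost (ties: larger combined bottleneck, then lower tunnel index).
#'
#' @param tunnel_sets list (one element per frame) of tunnel lists from
#'   [search_tunnels()].
#' @param slab a `membrane_slab` used to classify endpoints.
#' @return list of `open_conformation` objects: `frame_index`, `tunnels`
#'   (endpoint-classified), `pair` (indices into `tunnels`:
#'   intracellular, extracellular).
#' @export
select_open_conformations <- function(tunnel_sets, slab) {
  out <- list()
  for (tset in tunnel_sets) {
    if (!length(tset)) next
    tset <- lapply(tset, classify_endpoint, slab = slab)
    ic <- which(vapply(tset, `[[`, character(1), "endpoint") ==
                  "intracellular")
    ec <- which(vapply(tset, `[[`, character(1), "endpoint") ==
                  "extracellular")
    if (!length(ic) || !length(ec)) next
    combos <- expand.grid(ic = ic, ec = ec)
    cost <- vapply(seq_len(nrow(combos)), function(i)
      tset[[combos$ic[i]]]$cost + tset[[combos$ec[i]]]$cost, numeric(1))
    bott <- vapply(seq_len(nrow(combos)), function(i)
      tset[[combos$ic[i]]]$bottleneck_radius +
        tset[[combos$ec[i]]]$bottleneck_radius, numeric(1))
    best <- order(cost, -bott, combos$ic, combos$ec)[1]
    out[[length(out) + 1L]] <- structure(
      list(frame_index = tset[[1]]$frame_index,
           tunnels = tset,
           pair = c(intracellular = combos$ic[best],
                    extracellular = combos$ec[best])),
      class = "open_conformation")
  }
  out
}

#' @export
print.open_conformation <- function(x, ...) {
  cat(sprintf(
    "open_conformation frame %d: %d tunnels, selected pair cost %.3f\n",
    x$frame_index + 1L, length(x$tunnels),
    x$tunnels[[x$pair[1]]]$cost + x$tunnels[[x$pair[2]]]$cost))
  invisible(x)
}

#' Per-frame tunnel summary table
#'
#' @param tunnel_sets list of tunnel lists (endpoint-classified or not).
#' @return data.frame `(frame, tunnel, endpoint, length, bottleneck, cost,
#'   n_spheres)` with 0-based frame indices.
#' @export
tunnel_table <- function(tunnel_sets) {
  rows <- list()
  for (tset in tunnel_sets) for (i in seq_along(tset)) {
    t <- tset[[i]]
    rows[[length(rows) + 1L]] <- data.frame(
      frame = t$frame_index, tunnel = i,
      endpoint = t$endpoint %||% NA_character_,
      length = t$length, bottleneck = t$bottleneck_radius, cost = t$cost,
      n_spheres = nrow(t$spheres))
  }
  if (!length(rows))
    return(data.frame(frame = integer(), tunnel = integer(),
                      endpoint = character(), length = numeric(),
                      bottleneck = numeric(), cost = numeric(),
                      n_spheres = integer()))
  do.call(rbind, rows)
}
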