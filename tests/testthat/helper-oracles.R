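# Independent reference implementations used as oracles.  These deliberately
# share no code with the package internals they check.

# plain O(V^2) Dijkstra over an undirected edge list (from, to, w)
ref_dijkstra <- function(n_nodes, edges, source) {
  from <- c(edges[, 1], edges[, 2])
  to <- c(edges[, 2], edges[, 1])
  w <- c(edges[, 3], edges[, 3])
  adj <- split(seq_along(from), from)
  dist <- rep(Inf, n_nodes)
  dist[source] <- 0
  done <- logical(n_nodes)
  for (it in seq_len(n_nodes)) {
    cand <- ifelse(done, Inf, dist)
    u <- which.min(cand)
    if (!is.finite(cand[u])) break
    done[u] <- TRUE
    nb <- adj[[as.character(u)]]
    if (length(nb)) {
      relax <- dist[u] + w[nb]
      better <- relax < dist[to[nb]]
      dist[to[nb][better]] <- relax[better]
    }
  }
  dist
}

# naive Ward agglomeration (Lance-Williams on squared distances, reported on
# the distance scale), mirroring the stats::hclust "ward.D2" convention
ref_ward <- function(D) {
  n <- nrow(D)
  D2 <- D^2
  active <- seq_len(n)
  sizes <- rep(1, n)
  id <- -seq_len(n)                   # hclust convention: leaves negative
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bd <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (jj <= ii) next
      a <- active[ii]; b <- active[jj]
      if (D2[a, b] < bd) { bd <- D2[a, b]; best <- c(a, b) }
    }
    a <- best[1]; b <- best[2]
    pair <- sort(c(id[a], id[b]))
    merge[step, ] <- pair
    height[step] <- sqrt(bd)
    # Lance-Williams update for Ward on squared distances
    for (c in setdiff(active, c(a, b))) {
      na <- sizes[a]; nb <- sizes[b]; nc <- sizes[c]
      D2[a, c] <- D2[c, a] <-
        ((na + nc) * D2[a, c] + (nb + nc) * D2[b, c] - nc * D2[a, b]) /
        (na + nb + nc)
    }
    sizes[a] <- sizes[a] + sizes[b]
    id[a] <- step
    active <- setdiff(active, b)
  }
  list(merge = merge, height = height)
}

# brute-force in-plane scan for the maximal inscribed sphere radius at a
# fixed z: r(c) = min_i(|c - a_i| - vdw_i) maximised over a 2D grid
ref_slice_radius <- function(z, atom_xyz, atom_vdw, xy_range = 3,
                             step = 0.05, centre = c(0, 0)) {
  xs <- seq(centre[1] - xy_range, centre[1] + xy_range, by = step)
  ys <- seq(centre[2] - xy_range, centre[2] + xy_range, by = step)
  best <- -Inf; best_c <- c(NA, NA)
  for (x in xs) {
    d2xy <- (atom_xyz[, 1] - x)^2
    for (y in ys) {
      d <- sqrt(d2xy + (atom_xyz[, 2] - y)^2 + (atom_xyz[, 3] - z)^2)
      r <- min(d - atom_vdw)
      if (r > best) { best <- r; best_c <- c(x, y) }
    }
  }
  list(radius = best, centre = best_c)
}

# exhaustive simple-path enumeration within a weight budget, via igraph's
# all_simple_paths (independent of the package's pruned DFS)
ref_paths_within <- function(graph, source, sink, budget) {
  ap <- igraph::all_simple_paths(graph, from = source, to = sink)
  wmat <- igraph::as_adjacency_matrix(graph, attr = "weight", sparse = FALSE)
  lens <- vapply(ap, function(p) {
    idx <- as.integer(p)
    sum(wmat[cbind(idx[-length(idx)], idx[-1])])
  }, numeric(1))
  sum(lens <= budget + 1e-9)
}

# numerically exact 1D free-energy reference for a radial potential U(s):
# F(s) = U(s) - 2 kT ln s (+ const), evaluated on a grid
ref_radial_fes <- function(U_of_s, s_grid, kT) {
  f <- U_of_s(s_grid) - 2 * kT * log(s_grid)
  f - min(f)
}
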