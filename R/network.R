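#' Dynamical cross-correlation matrix of Calpha motions
#'
#' Computes the normalised covariance of 3D Calpha displacement vectors,
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2> <|dr_j|^2>)`, over a frame
#' window, after (optionally) superposing every frame onto the window-mean
#' structure so rigid-body motion does not masquerade as correlation.
#' Residues with vanishing variance (immobile after fitting) get zero
#' correlations and a warning.
#'
#' @param trajectory an `ip_trajectory` with one CA atom per residue.
#' @param window 0-based frame indices to use (default: all; >= 10 frames).
#' @param fit superpose frames onto the window mean first (default TRUE).
#' @return symmetric matrix `C` with unit diagonal, dimnames = residue
#'   indices; immobile residues listed in attribute `immobile`.
#' @export
correlation_matrix <- function(trajectory, window = NULL, fit = TRUE) {
  topo <- trajectory$topology
  ca <- select_atoms(topo, atom_names = "CA")
  res <- topo$atoms$residue_index[ca]
  if (anyDuplicated(res))
    stop_ip("input_error", "expected one CA per residue")
  window <- window %||% (seq_along(trajectory$frames) - 1L)
  if (length(window) < 10)
    stop_ip("input_error", "correlation window needs >= 10 frames")
  X <- lapply(window, function(fi)
    trajectory$frames[[fi + 1L]]$coords[ca, , drop = FALSE])
  if (fit) {
    for (iter in 1:2) {       # mean structure stabilises after one refit
      mean_xyz <- Reduce(`+`, X) / length(X)
      X <- lapply(X, function(x) superpose(x, mean_xyz)$fitted)
    }
  }
  mean_xyz <- Reduce(`+`, X) / length(X)
  D <- lapply(X, function(x) x - mean_xyz)     # displacements
  n <- length(ca)
  # cov_ij = mean over frames of dr_i . dr_j, summed over x,y,z
  cov <- matrix(0, n, n)
  for (d in D) cov <- cov + d %*% t(d)
  cov <- cov / length(D)
  v <- diag(cov)
  immobile <- which(v < 1e-12)
  if (length(immobile))
    warning(sprintf("immobile residue(s) with zero variance: %s",
                    paste(res[immobile], collapse = ", ")))
  s <- sqrt(pmax(v, 1e-300))
  C <- cov / outer(s, s)
  C[immobile, ] <- 0; C[, immobile] <- 0
  diag(C) <- 1
  dimnames(C) <- list(res, res)
  attr(C, "immobile") <- res[immobile]
  C
}

#' Build a contact-filtered correlation network
#'
#' Nodes are residues (Calpha); an edge (i, j) exists when any heavy-atom
#' pair of the two residues is within `contact_cut` in at least
#' `contact_fraction` of the window frames (consecutive residues allowed).
#' Edge weight is `w_ij = -ln |C_ij|`; pairs with `C_ij = 0` get no edge.
#'
#' @param C correlation matrix from [correlation_matrix()].
#' @param trajectory the `ip_trajectory` used for the contact criterion.
#' @param window 0-based frame indices (default: all).
#' @param contact_cut heavy-atom distance cutoff (A), default 4.5.
#' @param contact_fraction minimum occupancy, default 0.75.
#' @return a `correlation_network`: `nodes` (residue indices), `edges`
#'   (data.frame `i, j, correlation, weight`), `graph` (igraph object with
#'   vertex names = residue indices), `C`.
#' @export
build_network <- function(C, trajectory, window = NULL, contact_cut = 4.5,
                          contact_fraction = 0.75) {
  topo <- trajectory$topology
  res <- as.integer(rownames(C))
  window <- window %||% (seq_along(trajectory$frames) - 1L)
  heavy <- select_atoms(topo, segment = "protein")
  heavy <- heavy[toupper(topo$atoms$element[heavy]) != "H"]
  heavy <- heavy[topo$atoms$residue_index[heavy] %in% res]
  rfac <- factor(topo$atoms$residue_index[heavy], levels = res)
  n <- length(res)
  occ <- matrix(0L, n, n)
  for (fi in window) {
    xyz <- trajectory$frames[[fi + 1L]]$coords[heavy, , drop = FALSE]
    d2 <- dist2_xyz(xyz, xyz)
    hit <- d2 < contact_cut^2
    # residue-level any-atom-pair contact
    a <- rowsum(hit + 0, rfac, reorder = FALSE)          # res x atoms
    b <- t(rowsum(t(a > 0) + 0, rfac, reorder = FALSE))  # res x res
    occ <- occ + (b > 0)
  }
  frac <- occ / length(window)
  edges <- which(upper.tri(frac) & frac >= contact_fraction &
                   abs(C) > 0, arr.ind = TRUE)
  ed <- data.frame(i = res[edges[, 1]], j = res[edges[, 2]],
                   correlation = C[edges],
                   weight = -log(abs(C[edges])))
  gr <- igraph::graph_from_data_frame(
    data.frame(from = as.character(ed$i), to = as.character(ed$j)),
    directed = FALSE,
    vertices = data.frame(name = as.character(res)))
  igraph::E(gr)$weight <- ed$weight
  structure(list(nodes = res, edges = ed, graph = gr, C = C,
                 contact_cut = contact_cut,
                 contact_fraction = contact_fraction),
            class = "correlation_network")
}

#' Build a correlation network from an explicit edge list
#'
#' Bypasses the trajectory-derived contact filter: useful for analysing a
#' network defined elsewhere, or for validating path enumeration on known
#' graphs.  Either `weight` or `correlation` must be supplied (weights
#' derive from correlations as `-ln|C|`).
#'
#' @param edges data.frame with columns `i`, `j` and `weight` (or
#'   `correlation`).
#' @return a `correlation_network`.
#' @export
network_from_edges <- function(edges) {
  if (is.null(edges$weight)) {
    if (is.null(edges$correlation))
      stop_ip("input_error", "edges need a weight or correlation column")
    edges$weight <- -log(abs(edges$correlation))
  }
  if (any(edges$weight < 0))
    stop_ip("input_error", "edge weights must be >= 0")
  # collapse parallel edges to the lightest one
  key <- paste(pmin(edges$i, edges$j), pmax(edges$i, edges$j))
  edges <- edges[order(key, edges$weight), ]
  edges <- edges[!duplicated(paste(pmin(edges$i, edges$j),
                                   pmax(edges$i, edges$j))), ]
  res <- sort(unique(c(edges$i, edges$j)))
  gr <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$i), to = as.character(edges$j)),
    directed = FALSE,
    vertices = data.frame(name = as.character(res)))
  igraph::E(gr)$weight <- edges$weight
  structure(list(nodes = res, edges = edges, graph = gr, C = NULL,
                 contact_cut = NA_real_, contact_fraction = NA_real_),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  comp <- igraph::components(x$graph)
  cat(sprintf(
    "correlation_network: %d nodes, %d edges, %d component(s)\n",
    length(x$nodes), nrow(x$edges), comp$no))
  invisible(x)
}

#' Optimal and suboptimal paths between two residues
#'
#' The optimal path is the shortest path under the `-ln|C|` edge weights;
#' the suboptimal ensemble is the EXACT set of all simple paths whose total
#' weight is within `tolerance` of the optimum, enumerated by bounded
#' depth-first search with an admissible best-remaining-distance prune.
#'
#' @param network a `correlation_network`.
#' @param source,sink residue indices.
#' @param tolerance weight slack above the optimum (same `-ln|C|` units).
#' @return a `path_ensemble`: `source`, `sink`, `optimal_length`,
#'   `optimal_path` (residue sequence), `paths` (list of residue
#'   sequences, sorted by length), `lengths`, `count`.  Disconnected pairs
#'   give `count = 0` and `optimal_length = Inf`.
#' @export
suboptimal_paths <- function(network, source, sink, tolerance = 0.2) {
  gr <- network$graph
  vs <- igraph::V(gr)$name
  s <- match(as.character(source), vs)
  t <- match(as.character(sink), vs)
  if (is.na(s) || is.na(t))
    stop_ip("selection_error", "source/sink residue not in network")
  if (s == t) {
    return(structure(list(source = source, sink = sink,
                          optimal_length = 0,
                          optimal_path = source, paths = list(source),
                          lengths = 0, count = 1L),
                     class = "path_ensemble"))
  }
  dist_to_sink <- unname(igraph::distances(gr, v = vs[t])[1, ])
  if (!is.finite(dist_to_sink[s])) {
    return(structure(list(source = source, sink = sink,
                          optimal_length = Inf, optimal_path = integer(0),
                          paths = list(), lengths = numeric(0), count = 0L),
                     class = "path_ensemble"))
  }
  opt <- dist_to_sink[s]
  budget <- opt + tolerance + 1e-9
  adj <- igraph::as_adj_list(gr, mode = "all")
  adj <- lapply(adj, function(v) as.integer(v))
  wmat <- igraph::as_adjacency_matrix(gr, attr = "weight", sparse = TRUE)
  found <- new.env()
  found$paths <- vector("list", 0L)
  found$lengths <- numeric(0)
  visited <- logical(length(vs))
  dfs <- function(v, acc, trail) {
    if (v == t) {
      found$paths[[length(found$paths) + 1L]] <- trail
      found$lengths <- c(found$lengths, acc)
      return(invisible())
    }
    visited[v] <<- TRUE
    for (u in adj[[v]]) {
      if (visited[u]) next
      w <- acc + wmat[v, u]
      if (w + dist_to_sink[u] <= budget)
        dfs(u, w, c(trail, u))
    }
    visited[v] <<- FALSE
  }
  dfs(s, 0, s)
  ord <- order(found$lengths)
  res_paths <- lapply(found$paths[ord], function(p) as.integer(vs[p]))
  structure(list(source = source, sink = sink,
                 optimal_length = opt,
                 optimal_path = res_paths[[1]],
                 paths = res_paths, lengths = found$lengths[ord],
                 count = length(res_paths)),
            class = "path_ensemble")
}

#' @export
print.path_ensemble <- function(x, ...) {
  cat(sprintf(
    "path_ensemble %d -> %d: optimal length %.3f, %d path(s) in band\n",
    x$source, x$sink, x$optimal_length, x$count))
  invisible(x)
}

#' Source-sink coupling table
#'
#' One suboptimal-path count per (source, sink) combination, ranked by
#' decreasing count (the count measures dynamic coupling strength).
#'
#' @param network a `correlation_network`.
#' @param sources,sinks non-empty residue index vectors.
#' @param tolerance passed to [suboptimal_paths()].
#' @return data.frame `(source, sink, optimal_length, count, rank)`.
#' @export
coupling_table <- function(network, sources, sinks, tolerance = 0.2) {
  if (!length(sources) || !length(sinks))
    stop_ip("input_error", "sources and sinks must be non-empty")
  combos <- expand.grid(source = sources, sink = sinks)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    pe <- suboptimal_paths(network, combos$source[i], combos$sink[i],
                           tolerance)
    data.frame(source = combos$source[i], sink = combos$sink[i],
               optimal_length = pe$optimal_length, count = pe$count)
  })
  out <- do.call(rbind, rows)
  out$rank <- rank(-out$count, ties.method = "min")
  out[order(out$rank), ]
}
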