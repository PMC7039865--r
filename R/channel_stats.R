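#' Channel-lining residues of one tunnel
#'
#' A residue lines the tunnel when any of its atoms lies within
#' `contact_distance` of any tunnel sphere SURFACE, i.e.
#' `|atom - sphere_centre| - sphere_radius < contact_distance`
#' (strict `<`; Caver's default contact distance is 3.0 A).
#'
#' @param tunnel a `tunnel`.
#' @param frame the `ip_frame` the tunnel was computed on (same
#'   `frame_index`).
#' @param topology matching `ip_topology`.
#' @param contact_distance gap threshold (A), default 3.0.
#' @param heavy_only ignore hydrogens (default TRUE).
#' @return sorted integer vector of residue indices.
#' @export
lining_residues <- function(tunnel, frame, topology, contact_distance = 3.0,
                            heavy_only = TRUE) {
  if (!is.na(tunnel$frame_index) && !is.null(frame$frame_index) &&
      tunnel$frame_index != frame$frame_index)
    stop_ip("input_error", "tunnel frame %d does not match frame %d",
            tunnel$frame_index, frame$frame_index)
  rows <- select_atoms(topology, segment = "protein")
  if (heavy_only)
    rows <- rows[toupper(topology$atoms$element[rows]) != "H"]
  axyz <- frame$coords[rows, , drop = FALSE]
  sph <- as.matrix(tunnel$spheres[, c("x", "y", "z")])
  gap_min <- rep(Inf, length(rows))
  i <- 1L
  while (i <= nrow(sph)) {                     # chunk over spheres
    j <- min(i + 499L, nrow(sph))
    d <- sqrt(pmax(dist2_xyz(axyz, sph[i:j, , drop = FALSE]), 0))
    gap <- sweep(d, 2L, tunnel$spheres$radius[i:j], "-")
    gap_min <- pmin(gap_min, apply(gap, 1L, min))
    i <- j + 1L
  }
  hit <- gap_min < contact_distance
  sort(unique(topology$atoms$residue_index[rows[hit]]))
}

#' Lining-residue frequencies over open frames
#'
#' For every open conformation, the residues lining the selected
#' intracellular/extracellular tunnel pair are counted; counts are
#' normalised either to the maximum count (plot peaks at 1) or to the
#' number of open frames.
#'
#' @param open_conformations list from [select_open_conformations()].
#' @param trajectory the `ip_trajectory` the tunnels were computed on.
#' @param contact_distance gap threshold (A), default 3.0.
#' @param normalize `"max"` (default) or `"n_open"`.
#' @return data.frame `(residue_index, residue_name, raw_count, frequency)`
#'   sorted by residue index; only residues lining at least one open frame.
#' @export
lining_frequency <- function(open_conformations, trajectory,
                             contact_distance = 3.0,
                             normalize = c("max", "n_open")) {
  normalize <- match.arg(normalize)
  if (!length(open_conformations))
    stop_ip("analysis_error", "no open frames: lining frequency undefined")
  topo <- trajectory$topology
  counts <- integer(0)
  for (oc in open_conformations) {
    frame <- trajectory$frames[[oc$frame_index + 1L]]
    res <- unique(c(
      lining_residues(oc$tunnels[[oc$pair[1]]], frame, topo,
                      contact_distance),
      lining_residues(oc$tunnels[[oc$pair[2]]], frame, topo,
                      contact_distance)))
    key <- as.character(res)
    counts[key] <- ifelse(is.na(counts[key]), 0L, counts[key]) + 1L
  }
  ri <- as.integer(names(counts))
  denom <- if (normalize == "max") max(counts)
  else length(open_conformations)
  rn <- topo$residues$residue_name[match(ri, topo$residues$residue_index)]
  out <- data.frame(residue_index = ri, residue_name = rn,
                    raw_count = as.integer(counts),
                    frequency = as.numeric(counts) / denom)
  out[order(out$residue_index), ]
}

# pairwise RMSD over the union of two frames' lining-residue atoms
lining_rmsd_matrix <- function(open_conformations, trajectory,
                               contact_distance = 3.0, heavy_only = TRUE) {
  topo <- trajectory$topology
  n <- length(open_conformations)
  lin <- lapply(open_conformations, function(oc) {
    frame <- trajectory$frames[[oc$frame_index + 1L]]
    unique(c(lining_residues(oc$tunnels[[oc$pair[1]]], frame, topo,
                             contact_distance, heavy_only),
             lining_residues(oc$tunnels[[oc$pair[2]]], frame, topo,
                             contact_distance, heavy_only)))
  })
  prot <- select_atoms(topo, segment = "protein")
  if (heavy_only) prot <- prot[toupper(topo$atoms$element[prot]) != "H"]
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    res_union <- union(lin[[i]], lin[[j]])
    rows <- prot[topo$atoms$residue_index[prot] %in% res_union]
    xi <- trajectory$frames[[open_conformations[[i]]$frame_index + 1L]]$coords
    xj <- trajectory$frames[[open_conformations[[j]]$frame_index + 1L]]$coords
    D[i, j] <- D[j, i] <-
      sqrt(mean(rowSums((xi[rows, , drop = FALSE] -
                           xj[rows, , drop = FALSE])^2)))
  }
  D
}

#' Ward clustering of open-channel conformations
#'
#' Open frames (assumed pre-aligned to a common reference, e.g. via
#' [align_trajectory()]) are compared by the RMSD over the atoms of the
#' UNION of their lining residues; the resulting distance matrix is
#' clustered by Ward's method and cut at `threshold`.
#'
#' @param open_conformations list from [select_open_conformations()].
#' @param trajectory aligned `ip_trajectory`.
#' @param threshold dendrogram cut height (A), default 4.5.
#' @param contact_distance lining gap threshold (A).
#' @return list with `clusters` (list of `list(members, medoid, height)`
#'   where members/medoid are 0-based frame indices), `assignments`
#'   (integer per open frame), `hclust` (the fitted tree, `NULL` when
#'   fewer than 2 open frames) and `distance` (the RMSD matrix).
#' @export
cluster_channels <- function(open_conformations, trajectory,
                             threshold = 4.5, contact_distance = 3.0) {
  n <- length(open_conformations)
  frames_idx <- vapply(open_conformations, `[[`, integer(1), "frame_index")
  if (n < 2) {
    return(list(clusters = list(list(members = frames_idx,
                                     medoid = frames_idx[1] %||% NA_integer_,
                                     height = 0)),
                assignments = rep(1L, n), hclust = NULL,
                distance = matrix(0, n, n)))
  }
  D <- lining_rmsd_matrix(open_conformations, trajectory, contact_distance)
  hc <- stats::hclust(stats::as.dist(D), method = "ward.D2")
  assign <- stats::cutree(hc, h = threshold)
  clusters <- lapply(sort(unique(assign)), function(k) {
    mem <- which(assign == k)
    med <- mem[which.min(colSums(D[mem, mem, drop = FALSE]))]
    hmax <- if (length(mem) > 1)
      max(hc$height[apply(hc$merge, 1, function(m) {
        leaves <- tree_leaves(hc, m)
        all(leaves %in% mem)
      })]) else 0
    list(members = frames_idx[mem], medoid = frames_idx[med], height = hmax)
  })
  list(clusters = clusters, assignments = unname(assign), hclust = hc,
       distance = D)
}

# leaves under one merge row of an hclust tree
tree_leaves <- function(hc, m) {
  out <- integer(0)
  for (v in m) {
    if (v < 0) out <- c(out, -v)
    else out <- c(out, tree_leaves(hc, hc$merge[v, ]))
  }
  out
}

#' Averaged channel radius along z
#'
#' Pools the spheres of every selected tunnel pair of every open
#' conformation and averages sphere radii in contiguous z bins.
#'
#' @param open_conformations list from [select_open_conformations()].
#' @param bin_width bin width (A), default 1.0.
#' @return data.frame `(z_center, mean_radius, n_spheres)`.
#' @export
radius_profile_z <- function(open_conformations, bin_width = 1.0) {
  if (!length(open_conformations))
    stop_ip("analysis_error", "no open conformations: empty sphere pool")
  sph <- do.call(rbind, lapply(open_conformations, function(oc)
    rbind(oc$tunnels[[oc$pair[1]]]$spheres,
          oc$tunnels[[oc$pair[2]]]$spheres)))
  if (!nrow(sph)) stop_ip("analysis_error", "empty sphere pool")
  lo <- floor(min(sph$z) / bin_width) * bin_width
  bins <- floor((sph$z - lo) / bin_width)
  agg_mean <- tapply(sph$radius, bins, mean)
  agg_n <- tapply(sph$radius, bins, length)
  data.frame(z_center = lo + (as.integer(names(agg_mean)) + 0.5) * bin_width,
             mean_radius = as.numeric(agg_mean),
             n_spheres = as.integer(agg_n))
}
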