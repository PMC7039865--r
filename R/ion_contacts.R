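#' Ion-protein contact map
#'
#' For every frame, a (residue, ion) pair is counted once when any protein
#' atom of the residue lies strictly within `d_cut` of the ion
#' (residue-level per-frame binarisation).  Distances use the
#' minimum-image convention when the frame carries a box.
#'
#' @param trajectory an `ip_trajectory`.
#' @param ion_rows atom row positions of the ions (e.g. from
#'   [select_atoms()] with `segment = "ion"`).
#' @param protein_rows atom rows of the protein (default: all protein
#'   atoms).
#' @param d_cut contact distance (A), strict `<`, default 4.0.
#' @param frames optional 0-based frame indices restricting the partition
#'   (default: all frames).
#' @param partition_label label stored with the map (`"all"`, `"open"`,
#'   `"closed"`, ...).
#' @return an `ion_contact_map`: `counts` (residue x ion matrix of
#'   per-frame binarised contact counts), `per_residue` (number of frames
#'   in which the residue contacts ANY selected ion), `frequency`
#'   (`per_residue / n_frames`, in `[0, 1]`), `residue_index`, `ion_ids`,
#'   `n_frames`, `partition`.
#' @export
contact_map <- function(trajectory, ion_rows, protein_rows = NULL,
                        d_cut = 4.0, frames = NULL,
                        partition_label = "all") {
  topo <- trajectory$topology
  protein_rows <- protein_rows %||% select_atoms(topo, segment = "protein")
  if (!length(ion_rows)) stop_ip("selection_error", "empty ion selection")
  if (!length(protein_rows))
    stop_ip("selection_error", "empty protein selection")
  frames <- frames %||% (seq_along(trajectory$frames) - 1L)
  res_ids <- unique(topo$atoms$residue_index[protein_rows])
  res_fac <- factor(topo$atoms$residue_index[protein_rows],
                    levels = res_ids)
  counts <- matrix(0L, length(res_ids), length(ion_rows),
                   dimnames = list(res_ids, NULL))
  per_res <- setNames(integer(length(res_ids)), res_ids)
  for (fi in frames) {
    f <- trajectory$frames[[fi + 1L]]
    pxyz <- f$coords[protein_rows, , drop = FALSE]
    any_hit <- logical(length(res_ids))
    for (k in seq_along(ion_rows)) {
      dvec <- sweep(pxyz, 2, f$coords[ion_rows[k], ])
      dvec <- min_image(dvec, f$box)
      d <- sqrt(rowSums(dvec^2))
      hit_res <- unique(res_fac[d < d_cut])
      if (length(hit_res)) {
        counts[as.integer(hit_res), k] <- counts[as.integer(hit_res), k] + 1L
        any_hit[as.integer(hit_res)] <- TRUE
      }
    }
    per_res <- per_res + any_hit
  }
  structure(list(counts = counts,
                 per_residue = per_res,
                 frequency = as.numeric(per_res) / max(length(frames), 1L),
                 residue_index = res_ids,
                 ion_ids = ion_rows,
                 n_frames = length(frames),
                 partition = partition_label),
            class = "ion_contact_map")
}

#' @export
print.ion_contact_map <- function(x, ...) {
  cat(sprintf(
    "ion_contact_map (%s): %d residues x %d ions over %d frames, %d contacts\n",
    x$partition, nrow(x$counts), ncol(x$counts), x$n_frames,
    sum(x$counts)))
  invisible(x)
}

#' Per-ion z tracks with leaflet boundaries and entry detection
#'
#' Records each ion's z per frame together with the per-frame centre-of-mass
#' z of the phosphorus markers of each leaflet (leaflets split at the
#' marker z median).  An entry flag is set when the ion's z lies between
#' the leaflet COMs AND the ion's lateral (xy) distance to the pore axis is
#' below `lateral_envelope`.
#'
#' @param trajectory an `ip_trajectory`.
#' @param ion_rows atom rows of the tracked ions.
#' @param lipid_P_rows atom rows of the leaflet phosphorus markers.
#' @param pore_axis_xy in-plane position of the pore axis (A), default the
#'   mean xy of the protein.
#' @param lateral_envelope lateral cutoff (A), default 15.
#' @return data.frame `(ion, frame, x, y, z, z_lower_leaflet,
#'   z_upper_leaflet, entered)`; `ion` is the position within `ion_rows`.
#' @export
ion_z_tracks <- function(trajectory, ion_rows, lipid_P_rows,
                         pore_axis_xy = NULL, lateral_envelope = 15) {
  if (!length(lipid_P_rows))
    stop_ip("analysis_error", "no lipid phosphorus markers")
  if (!length(ion_rows)) stop_ip("selection_error", "empty ion selection")
  if (is.null(pore_axis_xy)) {
    prot <- select_atoms(trajectory$topology, segment = "protein")
    pore_axis_xy <- if (length(prot))
      colMeans(trajectory$frames[[1]]$coords[prot, 1:2, drop = FALSE])
    else c(0, 0)
  }
  rows <- list()
  for (t in seq_along(trajectory$frames)) {
    f <- trajectory$frames[[t]]
    pz <- f$coords[lipid_P_rows, 3]
    med <- stats::median(pz)
    z_lo <- mean(pz[pz <= med]); z_hi <- mean(pz[pz > med])
    if (!is.finite(z_hi)) z_hi <- z_lo   # all markers at one level
    ion_xyz <- f$coords[ion_rows, , drop = FALSE]
    lat <- sqrt((ion_xyz[, 1] - pore_axis_xy[1])^2 +
                (ion_xyz[, 2] - pore_axis_xy[2])^2)
    rows[[t]] <- data.frame(
      ion = seq_along(ion_rows), frame = f$frame_index,
      x = ion_xyz[, 1], y = ion_xyz[, 2], z = ion_xyz[, 3],
      z_lower_leaflet = z_lo, z_upper_leaflet = z_hi,
      entered = ion_xyz[, 3] > z_lo & ion_xyz[, 3] < z_hi &
        lat < lateral_envelope)
  }
  do.call(rbind, rows)
}

#' Difference between open- and closed-partition contact maps
#'
#' Both maps are first normalised within their own partition (per-frame
#' contact rate), then differenced residue-wise.
#'
#' @param map_open,map_closed `ion_contact_map`s over the same residue set.
#' @return data.frame `(residue_index, rate_open, rate_closed, difference)`
#'   sorted by decreasing `|difference|`.
#' @export
contact_map_difference <- function(map_open, map_closed) {
  if (!identical(map_open$residue_index, map_closed$residue_index))
    stop_ip("input_error", "contact maps cover different residue sets")
  r_open <- map_open$per_residue / max(map_open$n_frames, 1L)
  r_closed <- map_closed$per_residue / max(map_closed$n_frames, 1L)
  out <- data.frame(residue_index = map_open$residue_index,
                    rate_open = as.numeric(r_open),
                    rate_closed = as.numeric(r_closed),
                    difference = as.numeric(r_open - r_closed))
  out[order(-abs(out$difference)), ]
}
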