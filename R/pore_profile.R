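#' Define the transmembrane slab from anchor residues
#'
#' The slab is the z interval between the centres of mass of two groups of
#' Calpha atoms placed at the levels of the intracellular and extracellular
#' lipid head groups.  Bounds are swapped if needed so `z_lower < z_upper`.
#'
#' @param frame an `ip_frame`.
#' @param topology matching `ip_topology`.
#' @param lower_selection,upper_selection residue index vectors for the two
#'   anchor groups.
#' @param chain optional chain restriction.
#' @return a `membrane_slab` list with `z_lower`, `z_upper`.
#' @export
compute_slab <- function(frame, topology, lower_selection, upper_selection,
                         chain = NULL) {
  lo <- select_calpha(topology, lower_selection, chain)
  hi <- select_calpha(topology, upper_selection, chain)
  z1 <- mean(frame$coords[lo, 3]); z2 <- mean(frame$coords[hi, 3])
  membrane_slab(min(z1, z2), max(z1, z2))
}

#' Construct a membrane slab from explicit z bounds
#' @param z_lower,z_upper slab bounds (A), `z_lower < z_upper`.
#' @return a `membrane_slab` list.
#' @export
membrane_slab <- function(z_lower, z_upper) {
  if (!is_number(z_lower) || !is_number(z_upper) || z_lower >= z_upper)
    stop_ip("input_error", "slab needs z_lower < z_upper")
  structure(list(z_lower = z_lower, z_upper = z_upper),
            class = "membrane_slab")
}

# maximise r(c) = min_i(|c - a_i| - vdw_i) over in-plane centre c at fixed z.
# multi-start Nelder-Mead: previous slice centre plus 4 deterministic jitters
optimize_slice <- function(z, start_xy, atom_xyz, atom_vdw, r_cap,
                           jitter = 0.75) {
  near <- abs(atom_xyz[, 3] - z) < r_cap + max(atom_vdw) + 1
  if (!any(near))
    return(list(x = start_xy[1], y = start_xy[2], radius = r_cap,
                unbounded = TRUE))
  axyz <- atom_xyz[near, , drop = FALSE]
  avdw <- atom_vdw[near]
  obj <- function(p) {
    d <- sqrt((axyz[, 1] - p[1])^2 + (axyz[, 2] - p[2])^2 +
              (axyz[, 3] - z)^2)
    -min(d - avdw)
  }
  starts <- rbind(start_xy,
                  start_xy + c(jitter, 0), start_xy + c(-jitter, 0),
                  start_xy + c(0, jitter), start_xy + c(0, -jitter))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[s, ], obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-10, maxit = 400))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  r <- -best$value
  list(x = best$par[1], y = best$par[2], radius = min(max(r, 0), r_cap),
       unbounded = r >= r_cap)
}

#' Pore radius profile along the membrane normal
#'
#' For each z slice the in-plane centre of the maximal inscribed sphere is
#' found by multi-start local optimisation of
#' `r(c) = min_i (|c - a_i| - vdw_i)`, seeded from the previous slice's
#' centre (a HOLE-style sweep).  Radii are clamped at `r_cap`; a slice
#' reaching the cap is flagged unbounded (pore merged with bulk).
#'
#' @param frame an `ip_frame`.
#' @param topology matching `ip_topology`.
#' @param slab a `membrane_slab`; slices cover
#'   `[z_lower - z_margin, z_upper + z_margin]`.
#' @param seed_point length-3 start point (A); its z only anchors the sweep
#'   start slice.
#' @param slice_step slice spacing (A), default 0.5.
#' @param r_cap maximum reported radius (A), default 10.
#' @param include_lipids also treat lipid atoms as pore-bounding walls
#'   (default FALSE: protein atoms only).
#' @param z_margin extension beyond the slab on both sides (A).
#' @return a `pore_profile`: data.frame `slices` (`z, x, y, radius,
#'   unbounded`), `min_radius_in_slab`, `frame_index`, `slab`.
#' @export
profile_pore <- function(frame, topology, slab, seed_point,
                         slice_step = 0.5, r_cap = 10,
                         include_lipids = FALSE, z_margin = 2) {
  if (slice_step <= 0) stop_ip("input_error", "slice_step must be > 0")
  segs <- if (include_lipids) c("protein", "lipid") else "protein"
  rows <- select_atoms(topology, segment = segs)
  if (!length(rows)) stop_ip("selection_error", "no pore-bounding atoms")
  axyz <- frame$coords[rows, , drop = FALSE]
  avdw <- topology$atoms$vdw_radius[rows]
  seed_clear <- min(sqrt(rowSums(sweep(axyz, 2, seed_point)^2)) - avdw)
  if (seed_clear > r_cap)
    stop_ip("initialization_error",
            "seed point is outside the structure (clearance %.1f A)",
            seed_clear)
  zs <- seq(slab$z_lower - z_margin, slab$z_upper + z_margin,
            by = slice_step)
  # sweep outwards from the slice nearest the seed z
  i0 <- which.min(abs(zs - seed_point[3]))
  order_up <- i0:length(zs)
  order_dn <- if (i0 > 1) (i0 - 1):1 else integer(0)
  res <- vector("list", length(zs))
  centre <- seed_point[1:2]
  for (i in order_up) {
    res[[i]] <- optimize_slice(zs[i], centre, axyz, avdw, r_cap)
    centre <- c(res[[i]]$x, res[[i]]$y)
  }
  centre <- c(res[[i0]]$x, res[[i0]]$y)
  for (i in order_dn) {
    res[[i]] <- optimize_slice(zs[i], centre, axyz, avdw, r_cap)
    centre <- c(res[[i]]$x, res[[i]]$y)
  }
  slices <- data.frame(
    z = zs,
    x = vapply(res, `[[`, numeric(1), "x"),
    y = vapply(res, `[[`, numeric(1), "y"),
    radius = vapply(res, `[[`, numeric(1), "radius"),
    unbounded = vapply(res, `[[`, logical(1), "unbounded"))
  in_slab <- slices$z >= slab$z_lower & slices$z <= slab$z_upper
  structure(list(frame_index = frame$frame_index,
                 slices = slices,
                 min_radius_in_slab = if (any(in_slab))
                   min(slices$radius[in_slab]) else NA_real_,
                 slab = slab),
            class = "pore_profile")
}

#' @export
print.pore_profile <- function(x, ...) {
  cat(sprintf(
    "pore_profile frame %d: %d slices, min slab radius %.2f A\n",
    x$frame_index + 1L, nrow(x$slices), x$min_radius_in_slab))
  invisible(x)
}

#' Open/closed verdict for one pore profile
#'
#' A frame is open when every slice inside the slab has radius strictly
#' greater than `r_min` (default 1.8 A, the chloride ionic radius).
#'
#' @param profile a `pore_profile`.
#' @param slab optional `membrane_slab` overriding the one stored in the
#'   profile.
#' @param r_min threshold radius (A); strict `>` comparison.
#' @return logical.
#' @export
classify_open <- function(profile, slab = NULL, r_min = 1.8) {
  slab <- slab %||% profile$slab
  in_slab <- profile$slices$z >= slab$z_lower &
    profile$slices$z <= slab$z_upper
  if (!any(in_slab))
    stop_ip("analysis_error", "profile has no slices inside the slab")
  all(profile$slices$radius[in_slab] > r_min)
}

#' Screen every frame of a trajectory for an open pore
#'
#' @param trajectory an `ip_trajectory`.
#' @param slab a `membrane_slab`.
#' @param seed_point length-3 start point for the profiler.
#' @param r_min open threshold (A), strict `>`.
#' @param ... passed to [profile_pore()].
#' @return data.frame `(frame, min_radius_in_slab, open)` with 0-based
#'   frame indices; profiles in attribute `profiles`.
#' @export
screen_open_frames <- function(trajectory, slab, seed_point, r_min = 1.8,
                               ...) {
  profiles <- lapply(trajectory$frames, function(f)
    profile_pore(f, trajectory$topology, slab, seed_point, ...))
  out <- data.frame(
    frame = vapply(profiles, `[[`, integer(1), "frame_index"),
    min_radius_in_slab = vapply(profiles, `[[`, numeric(1),
                                "min_radius_in_slab"),
    open = vapply(profiles, classify_open, logical(1), r_min = r_min))
  attr(out, "profiles") <- profiles
  out
}
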