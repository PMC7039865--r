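# ---------------------------------------------------------------------------
# Synthetic ground-truth trajectory generators.
#
# Every downstream stage is validated against trajectories built here, whose
# correct answers are known analytically from the generator parameters rather
# than from running the analysis itself: the channel generator places rings of
# pseudo-atoms so the true maximal inscribed pore radius per slice IS the
# requested radius profile; ion tracks can be scripted through waypoints so
# contact counts are known exactly; residue motions are drawn with a
# prescribed block correlation structure.
# ---------------------------------------------------------------------------

# run expr with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic membrane-embedded channel
#'
#' Describes a stack of atom rings centred on the z axis.  For slice `j` at
#' height `z_j`, ring atoms are placed at centre distance
#' `radius_profile(z_j, frame) + atom_vdw` from the axis, so the true
#' maximal inscribed pore radius at that slice equals
#' `radius_profile(z_j, frame)` exactly — the analytic oracle for the pore
#' profiler.
#'
#' @param n_slices number of rings along z.
#' @param slice_spacing ring spacing (A).
#' @param atoms_per_ring atoms per ring (>= 6 so the ring is effectively
#'   closed at typical vdW radii).
#' @param radius_profile `function(z, frame)` returning the target pore
#'   radius (A, > 0) at height `z` for 0-based frame `frame`; may be
#'   vectorised in `z`.
#' @param atom_vdw vdW radius of the wall pseudo-atoms (A).
#' @param z0 z of the first ring (A).
#' @param seed RNG seed (reserved; ring placement is deterministic).
#' @return a `channel_spec` list.
#' @export
channel_spec <- function(n_slices, slice_spacing, atoms_per_ring,
                         radius_profile, atom_vdw = 1.5, z0 = 0, seed = 1L) {
  if (atoms_per_ring < 6)
    stop_ip("spec_error", "atoms_per_ring must be >= 6 (got %d)",
            atoms_per_ring)
  if (!is.function(radius_profile))
    stop_ip("spec_error", "radius_profile must be a function(z, frame)")
  if (n_slices < 2 || slice_spacing <= 0 || atom_vdw <= 0)
    stop_ip("spec_error", "invalid channel geometry")
  structure(list(n_slices = as.integer(n_slices),
                 slice_spacing = slice_spacing,
                 atoms_per_ring = as.integer(atoms_per_ring),
                 radius_profile = radius_profile, atom_vdw = atom_vdw,
                 z0 = z0, seed = as.integer(seed)),
            class = "channel_spec")
}

#' Generate a synthetic channel trajectory
#'
#' @param spec a [channel_spec()].
#' @param n_frames number of frames.
#' @return an `ip_trajectory`; one ring = one protein residue (`ALA`).
#'   The slice z positions are stored in attribute `slice_z`.
#' @export
make_channel_trajectory <- function(spec, n_frames) {
  stopifnot(inherits(spec, "channel_spec"))
  zs <- spec$z0 + (seq_len(spec$n_slices) - 1L) * spec$slice_spacing
  m <- spec$atoms_per_ring
  # stagger alternate rings so ring gaps do not align axially
  ang0 <- rep(c(0, pi / m), length.out = spec$n_slices)
  ang <- lapply(seq_len(spec$n_slices), function(j)
    ang0[j] + 2 * pi * (0:(m - 1)) / m)
  atoms <- data.frame(
    name = sprintf("C%02d", rep(seq_len(m), times = spec$n_slices)),
    element = "C",
    vdw_radius = spec$atom_vdw,
    residue_index = rep(seq_len(spec$n_slices), each = m),
    residue_name = "ALA",
    chain = "A",
    stringsAsFactors = FALSE)
  frames <- lapply(seq_len(n_frames) - 1L, function(fr) {
    r_true <- vapply(zs, function(z) spec$radius_profile(z, fr), numeric(1))
    if (any(!is.finite(r_true)) || any(r_true <= 0))
      stop_ip("spec_error",
              "radius_profile must be positive everywhere (frame %d)", fr)
    ring_r <- r_true + spec$atom_vdw
    xyz <- do.call(rbind, lapply(seq_len(spec$n_slices), function(j)
      cbind(ring_r[j] * cos(ang[[j]]), ring_r[j] * sin(ang[[j]]), zs[j])))
    ip_frame(xyz, frame_index = fr)
  })
  out <- ip_trajectory(ip_topology(atoms), frames)
  attr(out, "slice_z") <- zs
  out
}

#' Generate phosphorus-like membrane leaflet markers
#'
#' Scatters `n_per_leaflet` lipid-class marker atoms (name `P`) in each
#' leaflet plane.  In-plane positions are uniform; z jitter is recentred so
#' each leaflet's centre of mass sits exactly at the requested height.
#'
#' @param z_lower_leaflet,z_upper_leaflet leaflet COM heights (A),
#'   lower < upper.
#' @param n_per_leaflet markers per leaflet (>= 1).
#' @param seed RNG seed.
#' @param xy_half_width half-width of the scattered square patch (A).
#' @param z_jitter s.d. of z scatter before recentring (A).
#' @return list with `topology` (lipid markers only) and `frame`.
#' @export
make_membrane_markers <- function(z_lower_leaflet, z_upper_leaflet,
                                  n_per_leaflet, seed = 1L,
                                  xy_half_width = 30, z_jitter = 1) {
  if (z_lower_leaflet >= z_upper_leaflet)
    stop_ip("spec_error", "z_lower_leaflet must be < z_upper_leaflet")
  if (n_per_leaflet < 1) stop_ip("spec_error", "n_per_leaflet must be >= 1")
  with_seed(seed, {
    one <- function(zc, res0) {
      x <- runif(n_per_leaflet, -xy_half_width, xy_half_width)
      y <- runif(n_per_leaflet, -xy_half_width, xy_half_width)
      z <- zc + rnorm(n_per_leaflet, 0, z_jitter)
      z <- z - mean(z) + zc
      list(xyz = cbind(x, y, z), res = res0 + seq_len(n_per_leaflet))
    }
    lo <- one(z_lower_leaflet, 0L)
    hi <- one(z_upper_leaflet, n_per_leaflet)
    atoms <- data.frame(
      name = "P", element = "P", vdw_radius = 1.8,
      residue_index = c(lo$res, hi$res),
      residue_name = "POPC", chain = "M",
      stringsAsFactors = FALSE)
    list(topology = ip_topology(atoms),
         frame = ip_frame(rbind(lo$xyz, hi$xyz)))
  })
}

#' Specification of random-walk ion tracks
#'
#' Ions perform reflecting Gaussian random walks inside an orthorhombic box;
#' `waypoints` deterministically override positions at given frames, so
#' scripted approach segments yield exactly known contact counts.
#'
#' @param n_ions number of ions (0 allowed).
#' @param step_sigma per-frame displacement s.d. (A), > 0.
#' @param axial_bias optional per-frame drift along z (A).
#' @param reflecting_box box lengths (A); walks reflect at `[0, box]`.
#' @param seed RNG seed.
#' @param start optional `n_ions x 3` start positions; default random in box.
#' @param species residue/atom name for the ions (e.g. `"CLA"` chloride,
#'   `"POT"` potassium).
#' @param waypoints optional data.frame `(ion, frame, x, y, z)` with 1-based
#'   ion ids and 0-based frames.
#' @return an `ion_spec` list.
#' @export
ion_spec <- function(n_ions, step_sigma, axial_bias = 0,
                     reflecting_box = c(60, 60, 120), seed = 1L,
                     start = NULL, species = "CLA", waypoints = NULL) {
  if (step_sigma <= 0) stop_ip("spec_error", "step_sigma must be > 0")
  if (n_ions < 0) stop_ip("spec_error", "n_ions must be >= 0")
  if (!is.null(waypoints)) {
    need <- c("ion", "frame", "x", "y", "z")
    if (!all(need %in% names(waypoints)))
      stop_ip("spec_error", "waypoints needs columns %s",
              paste(need, collapse = ", "))
  }
  structure(list(n_ions = as.integer(n_ions), step_sigma = step_sigma,
                 axial_bias = axial_bias,
                 reflecting_box = as.numeric(reflecting_box),
                 seed = as.integer(seed), start = start,
                 species = species, waypoints = waypoints),
            class = "ion_spec")
}

reflect_into <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}

#' Generate ion random-walk tracks
#'
#' @param spec an [ion_spec()].
#' @param n_frames number of frames.
#' @return list with `trajectory` (ion-only `ip_trajectory`) and `truth`
#'   (data.frame `ion, frame, x, y, z, scripted`).
#' @export
make_ion_tracks <- function(spec, n_frames) {
  stopifnot(inherits(spec, "ion_spec"))
  box <- spec$reflecting_box
  n <- spec$n_ions
  el <- guess_element(rep(spec$species, n))
  atoms <- data.frame(
    name = rep(spec$species, n), element = el,
    vdw_radius = if (n) assign_vdw(el, vdw_radii()) else numeric(0),
    residue_index = seq_len(n), residue_name = rep(spec$species, n),
    chain = rep("I", n), stringsAsFactors = FALSE)
  pos_list <- with_seed(spec$seed, {
    pos <- spec$start %||%
      cbind(runif(n, 0, box[1]), runif(n, 0, box[2]), runif(n, 0, box[3]))
    out <- vector("list", n_frames)
    for (t in seq_len(n_frames)) {
      if (t > 1L && n > 0L) {
        step <- matrix(rnorm(3 * n, 0, spec$step_sigma), ncol = 3)
        step[, 3] <- step[, 3] + spec$axial_bias
        pos <- pos + step
        for (k in 1:3) pos[, k] <- reflect_into(pos[, k], 0, box[k])
      }
      out[[t]] <- pos
    }
    out
  })
  scripted <- matrix(FALSE, n_frames, max(n, 1L))
  if (!is.null(spec$waypoints) && n > 0L) {
    wp <- spec$waypoints
    for (i in seq_len(nrow(wp))) {
      t <- wp$frame[i] + 1L
      if (t >= 1L && t <= n_frames && wp$ion[i] >= 1L && wp$ion[i] <= n) {
        pos_list[[t]][wp$ion[i], ] <- c(wp$x[i], wp$y[i], wp$z[i])
        scripted[t, wp$ion[i]] <- TRUE
      }
    }
  }
  frames <- lapply(seq_len(n_frames), function(t)
    ip_frame(pos_list[[t]], frame_index = t - 1L, box = box))
  truth <- if (n > 0L) do.call(rbind, lapply(seq_len(n_frames), function(t)
    data.frame(ion = seq_len(n), frame = t - 1L,
               x = pos_list[[t]][, 1], y = pos_list[[t]][, 2],
               z = pos_list[[t]][, 3], scripted = scripted[t, seq_len(n)])))
  else data.frame(ion = integer(), frame = integer(), x = numeric(),
                  y = numeric(), z = numeric(), scripted = logical())
  list(trajectory = ip_trajectory(ip_topology(atoms), frames), truth = truth)
}

#' Specification of block-correlated residue motions
#'
#' @param n_residues chain length.
#' @param n_frames number of frames (>= 2).
#' @param block_structure list of blocks, each `list(residues =, rho =)`
#'   with `rho` in (0, 1]; residues outside every block move independently.
#' @param noise_sigma displacement s.d. per axis (A).
#' @param seed RNG seed.
#' @return a `correlated_motion_spec` list.
#' @export
correlated_motion_spec <- function(n_residues, n_frames, block_structure,
                                   noise_sigma = 0.5, seed = 1L) {
  if (n_frames < 2)
    stop_ip("spec_error", "correlation needs n_frames >= 2")
  seen <- integer(0)
  for (b in block_structure) {
    if (is.null(b$residues) || is.null(b$rho))
      stop_ip("spec_error", "each block needs residues and rho")
    if (b$rho <= 0 || b$rho > 1)
      stop_ip("spec_error",
              "block rho must lie in (0, 1] for a valid covariance")
    if (any(b$residues %in% seen))
      stop_ip("spec_error", "blocks must not overlap")
    seen <- c(seen, b$residues)
  }
  if (length(seen) && max(seen) > n_residues)
    stop_ip("spec_error", "block residue outside 1..n_residues")
  structure(list(n_residues = as.integer(n_residues),
                 n_frames = as.integer(n_frames),
                 block_structure = block_structure,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "correlated_motion_spec")
}

#' Generate a Calpha-only trajectory with block-correlated motions
#'
#' The base geometry is a straight chain with 3.8 A spacing; per-frame,
#' per-axis displacements of residues sharing a block have correlation
#' `rho` (shared factor construction `sqrt(rho) Z_block +
#' sqrt(1 - rho) E_i`), and ~0 across blocks.
#'
#' @param spec a [correlated_motion_spec()].
#' @return an `ip_trajectory` (one CA atom per GLY residue).
#' @export
make_correlated_trajectory <- function(spec) {
  stopifnot(inherits(spec, "correlated_motion_spec"))
  nr <- spec$n_residues; nf <- spec$n_frames
  base <- cbind(3.8 * (seq_len(nr) - 1L), 0, 0)
  block_of <- integer(nr)
  rho <- rep(0, nr)
  for (bi in seq_along(spec$block_structure)) {
    b <- spec$block_structure[[bi]]
    block_of[b$residues] <- bi
    rho[b$residues] <- b$rho
  }
  atoms <- data.frame(name = "CA", element = "C", vdw_radius = 1.7,
                      residue_index = seq_len(nr), residue_name = "GLY",
                      chain = "A", stringsAsFactors = FALSE)
  frames <- with_seed(spec$seed, {
    nb <- length(spec$block_structure)
    lapply(seq_len(nf), function(t) {
      zb <- matrix(rnorm(3 * max(nb, 1L)), ncol = 3)   # shared block factors
      ei <- matrix(rnorm(3 * nr), ncol = 3)            # independent parts
      disp <- ei
      inb <- block_of > 0L
      if (any(inb))
        disp[inb, ] <- sqrt(rho[inb]) * zb[block_of[inb], , drop = FALSE] +
          sqrt(1 - rho[inb]) * ei[inb, , drop = FALSE]
      ip_frame(base + spec$noise_sigma * disp, frame_index = t - 1L)
    })
  })
  ip_trajectory(ip_topology(atoms), frames)
}

#' Merge two systems frame-by-frame
#'
#' Concatenates the atom tables and per-frame coordinates of two
#' trajectories with equal frame counts (e.g. a synthetic channel plus ion
#' tracks plus membrane markers).
#'
#' @param a,b `ip_trajectory` objects with the same number of frames.
#' @return the combined `ip_trajectory` (atoms of `a` first).
#' @export
merge_trajectories <- function(a, b) {
  if (n_frames(a) != n_frames(b))
    stop_ip("input_error", "trajectories differ in frame count")
  cols <- c("name", "element", "vdw_radius", "residue_index",
            "residue_name", "chain", "segment_class")
  atoms <- rbind(a$topology$atoms[, cols], b$topology$atoms[, cols])
  frames <- lapply(seq_len(n_frames(a)), function(i)
    ip_frame(rbind(a$frames[[i]]$coords, b$frames[[i]]$coords),
             frame_index = i - 1L,
             box = a$frames[[i]]$box %||% b$frames[[i]]$box))
  ip_trajectory(ip_topology(atoms), frames)
}

#' Constant-plus-breathing radius profile
#'
#' Convenience constructor for [channel_spec()] radius profiles: a baseline
#' z profile whose minimum alternates (or oscillates) across frames.
#'
#' @param baseline `function(z)` giving the frame-independent profile (A).
#' @param amplitude breathing amplitude (A) added as
#'   `amplitude * sin(2 * pi * frame / period)`.
#' @param period breathing period in frames.
#' @return `function(z, frame)`.
#' @export
breathing_profile <- function(baseline, amplitude = 0, period = 2) {
  function(z, frame) baseline(z) + amplitude * sin(2 * pi * frame / period)
}
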