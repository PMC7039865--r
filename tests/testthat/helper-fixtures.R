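# Shared fixture builders (all generated in code; nothing on disk).

# standard small test channel: rings along z in [0, z_len]
fix_channel <- function(profile, n_frames = 1, n_slices = 16,
                        spacing = 1.5, apr = 16, vdw = 1.5) {
  make_channel_trajectory(
    channel_spec(n_slices = n_slices, slice_spacing = spacing,
                 atoms_per_ring = apr, radius_profile = profile,
                 atom_vdw = vdw),
    n_frames)
}

# slab strictly inside the channel so mouth exits classify as IC/EC
fix_slab <- function(trajectory) {
  zs <- attr(trajectory, "slice_z")
  membrane_slab(zs[2], zs[length(zs) - 1])
}

# a hand-built tunnel object (for endpoint / stats tests)
fix_tunnel <- function(centres, radii, frame_index = 0L) {
  centres <- matrix(centres, ncol = 3)
  len <- if (nrow(centres) > 1)
    sum(sqrt(rowSums(diff(centres)^2))) else 0
  structure(list(frame_index = frame_index,
                 spheres = data.frame(x = centres[, 1], y = centres[, 2],
                                      z = centres[, 3], radius = radii),
                 length = len,
                 bottleneck_radius = min(radii),
                 cost = len / min(radii)^2,
                 endpoint = NA_character_, n_members = 1L),
            class = "tunnel")
}

# minimal protein topology: one atom per residue at given coordinates
fix_point_topology <- function(xyz, residue_name = "GLY", atom_name = "CA",
                               element = "C", chain = "A") {
  n <- nrow(xyz)
  ip_topology(data.frame(
    name = atom_name, element = element, vdw_radius = 1.7,
    residue_index = seq_len(n), residue_name = residue_name, chain = chain,
    stringsAsFactors = FALSE))
}

# write a small PDB with full control over the raw lines
fix_write_pdb <- function(path, lines) {
  writeLines(c(lines, "END"), path)
  path
}

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          occ = 1, b = 0, element = "", alt = " ") {
  sprintf("ATOM  %5d %-4s%1s%-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resname, chain, resno, x, y, z, occ, b, element)
}

# scripted system: a few fixed protein atoms plus waypoint-driven ions
scripted_system <- function(n_frames = 20, ion_xyz_by_frame, species = "CLA",
                            protein_xyz = rbind(c(10, 10, 30))) {
  ntop <- fix_point_topology(protein_xyz)
  prot_frames <- lapply(seq_len(n_frames) - 1L, function(i)
    ip_frame(protein_xyz, i))
  prot <- ip_trajectory(ntop, prot_frames)
  n_ions <- nrow(ion_xyz_by_frame[[1]])
  wp <- do.call(rbind, lapply(seq_len(n_frames), function(t)
    data.frame(ion = seq_len(n_ions), frame = t - 1L,
               x = ion_xyz_by_frame[[t]][, 1],
               y = ion_xyz_by_frame[[t]][, 2],
               z = ion_xyz_by_frame[[t]][, 3])))
  ions <- make_ion_tracks(ion_spec(n_ions, 0.5, seed = 1,
                                   reflecting_box = c(60, 60, 60),
                                   species = species, waypoints = wp),
                          n_frames)
  merge_trajectories(prot, ions$trajectory)
}


make_open_conf_set <- function(n_per_geom = 2, shift = 3, seed = 1) {
  # frames with an axial channel vs a laterally displaced channel
  set.seed(seed)
  base <- fix_channel(function(z, fr) 2.5, n_frames = 1, n_slices = 8,
                      spacing = 1.5, apr = 12)
  topo <- base$topology
  frames <- list(); ocs <- list()
  n_tot <- 2 * n_per_geom
  for (i in seq_len(n_tot)) {
    dx <- if (i > n_per_geom) shift else 0
    xyz <- base$frames[[1]]$coords
    xyz[, 1] <- xyz[, 1] + dx + rnorm(1, 0, 0.02)
    frames[[i]] <- ip_frame(xyz, i - 1L)
    t_ic <- fix_tunnel(cbind(dx, 0, c(6, 1)), c(2.4, 2.4), i - 1L)
    t_ec <- fix_tunnel(cbind(dx, 0, c(6, 10)), c(2.4, 2.4), i - 1L)
    ocs[[i]] <- structure(list(frame_index = i - 1L,
                               tunnels = list(t_ic, t_ec),
                               pair = c(intracellular = 1L,
                                        extracellular = 2L)),
                          class = "open_conformation")
  }
  list(trajectory = ip_trajectory(topo, frames), ocs = ocs)
}

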