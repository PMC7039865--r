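test_that("contact counts equal the waypoint script exactly at a strict cutoff", {
  # ion sits at 3.9 A from the residue's only atom for exactly 7 frames
  pos <- lapply(1:20, function(t)
    if (t <= 7) rbind(c(10 + 3.9, 10, 30)) else rbind(c(50, 50, 50)))
  tr <- scripted_system(20, pos)
  ions <- select_atoms(tr$topology, segment = "ion")
  cm <- contact_map(tr, ions, d_cut = 4.0)
  expect_equal(unname(cm$per_residue["1"]), 7)
  # exactly at the cutoff: strict "<" counts zero
  pos0 <- lapply(1:20, function(t) rbind(c(10 + 4.0, 10, 30)))
  tr0 <- scripted_system(20, pos0)
  cm0 <- contact_map(tr0, select_atoms(tr0$topology, segment = "ion"),
                     d_cut = 4.0)
  expect_equal(sum(cm0$counts), 0)
})

test_that("contacts are residue-level: one count per frame regardless of atoms", {
  # two atoms of the same residue both within 3 A of the ion
  prot_xyz <- rbind(c(10, 10, 30), c(10, 11, 30))
  ntop <- ip_topology(data.frame(
    name = c("CA", "CB"), element = "C", vdw_radius = 1.7,
    residue_index = 1L, residue_name = "GLY", chain = "A"))
  frames <- lapply(0:4, function(i)
    ip_frame(rbind(prot_xyz, c(10, 10.5, 31))))
  ion_atoms <- data.frame(name = "CLA", element = "CL", vdw_radius = 1.75,
                          residue_index = 2L, residue_name = "CLA",
                          chain = "I")
  topo <- ip_topology(rbind(ntop$atoms[, 1:6], ion_atoms))
  tr <- ip_trajectory(topo, frames)
  cm <- contact_map(tr, ion_rows = 3L, d_cut = 3.0)
  expect_equal(unname(cm$per_residue["1"]), 5)   # not 10
  expect_true(all(cm$counts <= 5))
})

test_that("open and closed partitions add up to the all-frame map", {
  set.seed(8)
  pos <- lapply(1:30, function(t)
    rbind(c(10 + runif(1, 3, 6), 10, 30), c(runif(1, 0, 60), 20, 40)))
  tr <- scripted_system(30, pos)
  ions <- select_atoms(tr$topology, segment = "ion")
  open_frames <- c(0, 4, 7, 11, 25)
  closed_frames <- setdiff(0:29, open_frames)
  m_all <- contact_map(tr, ions)
  m_open <- contact_map(tr, ions, frames = open_frames,
                        partition_label = "open")
  m_closed <- contact_map(tr, ions, frames = closed_frames,
                          partition_label = "closed")
  expect_equal(m_open$counts + m_closed$counts, m_all$counts)
  expect_equal(m_open$per_residue + m_closed$per_residue, m_all$per_residue)
})

test_that("contact frequencies are invariant under rigid motion of frames", {
  pos <- lapply(1:10, function(t) rbind(c(10 + 3.5, 10, 30)))
  tr <- scripted_system(10, pos)
  ions <- select_atoms(tr$topology, segment = "ion")
  f1 <- contact_map(tr, ions)$frequency
  th <- 0.9
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  for (i in seq_along(tr$frames))
    tr$frames[[i]]$coords <- tr$frames[[i]]$coords %*% t(Rz) + 5
  f2 <- contact_map(tr, ions)$frequency
  expect_equal(f1, f2)
})

test_that("minimum-image convention sees contacts across the box boundary", {
  topo_atoms <- data.frame(
    name = c("CA", "CLA"), element = c("C", "CL"),
    vdw_radius = c(1.7, 1.75), residue_index = 1:2,
    residue_name = c("GLY", "CLA"), chain = c("A", "I"))
  topo <- ip_topology(topo_atoms)
  fr <- ip_frame(rbind(c(1, 30, 30), c(59, 30, 30)), box = c(60, 60, 60))
  tr <- ip_trajectory(topo, list(fr))
  cm <- contact_map(tr, ion_rows = 2L, d_cut = 4.0)   # wrapped distance 2
  expect_equal(sum(cm$counts), 1)
})

test_that("ion z tracks flag membrane entry inside the lateral envelope", {
  mk <- make_membrane_markers(60, 100, 60, seed = 12)
  n_fr <- 30
  mk_frames <- lapply(seq_len(n_fr) - 1L, function(i)
    ip_frame(mk$frame$coords, i))
  lip <- ip_trajectory(mk$topology, mk_frames)
  # scripted chloride rises z = 50 -> 80 near the axis; a second chloride
  # stays at z = 30
  zpath <- seq(50, 80, length.out = n_fr)
  pos <- lapply(seq_len(n_fr), function(t)
    rbind(c(0, 0, zpath[t]), c(0, 0, 30)))
  wp <- do.call(rbind, lapply(seq_len(n_fr), function(t)
    data.frame(ion = 1:2, frame = t - 1L, x = pos[[t]][, 1],
               y = pos[[t]][, 2], z = pos[[t]][, 3])))
  ions <- make_ion_tracks(ion_spec(2, 0.5, seed = 2, waypoints = wp,
                                   reflecting_box = c(60, 60, 120)), n_fr)
  tr <- merge_trajectories(lip, ions$trajectory)
  tracks <- ion_z_tracks(tr,
                         ion_rows = select_atoms(tr$topology, segment = "ion"),
                         lipid_P_rows = select_atoms(tr$topology,
                                                     atom_names = "P"),
                         pore_axis_xy = c(0, 0))
  expect_equal(unique(round(tracks$z_lower_leaflet, 6)), 60)
  expect_equal(unique(round(tracks$z_upper_leaflet, 6)), 100)
  t1 <- subset(tracks, ion == 1)
  first_in <- min(t1$frame[t1$entered])
  expect_equal(first_in, min(which(zpath > 60)) - 1L)
  expect_false(any(subset(tracks, ion == 2)$entered))
})

test_that("potassium negative-control tracks never enter", {
  mk <- make_membrane_markers(60, 100, 40, seed = 13)
  n_fr <- 25
  lip <- ip_trajectory(mk$topology,
                       lapply(seq_len(n_fr) - 1L, function(i)
                         ip_frame(mk$frame$coords, i)))
  pot <- make_ion_tracks(ion_spec(3, 1.0, seed = 6, species = "POT",
                                  reflecting_box = c(60, 60, 50),
                                  start = cbind(runif(3, -30, 30),
                                                runif(3, -30, 30),
                                                runif(3, 5, 45))), n_fr)
  tr <- merge_trajectories(lip, pot$trajectory)
  tracks <- ion_z_tracks(tr,
                         select_atoms(tr$topology, segment = "ion"),
                         select_atoms(tr$topology, atom_names = "P"),
                         pore_axis_xy = c(0, 0))
  expect_false(any(tracks$entered))   # walks capped below the membrane
})

test_that("contact-map differences rank scripted open-only contacts first", {
  prot_xyz <- rbind(c(10, 10, 30), c(20, 20, 30))
  pos_open <- rbind(c(13.5, 10, 30))    # near residue 1 only
  pos_far <- rbind(c(50, 50, 50))
  pos <- lapply(1:20, function(t) if (t <= 10) pos_open else pos_far)
  tr <- scripted_system(20, pos, protein_xyz = prot_xyz)
  ions <- select_atoms(tr$topology, segment = "ion")
  m_open <- contact_map(tr, ions, frames = 0:9, partition_label = "open")
  m_closed <- contact_map(tr, ions, frames = 10:19,
                          partition_label = "closed")
  d <- contact_map_difference(m_open, m_closed)
  expect_equal(d$residue_index[1], 1)
  expect_equal(d$difference[1], 1.0)    # contacted 100% open, 0% closed
  same <- contact_map_difference(m_open, m_open)
  expect_true(all(same$difference == 0))
  m_other <- contact_map(scripted_system(5, lapply(1:5, function(t)
    rbind(c(0, 0, 0)))), 2L)
  expect_error(contact_map_difference(m_open, m_other),
               class = "input_error")
})

test_that("partition rates difference follows the arithmetic definition", {
  prot_xyz <- rbind(c(10, 10, 30))
  # contacted in 50% of 10 open frames and 10% of 10 closed frames
  pos <- lapply(1:20, function(t) {
    near <- rbind(c(12, 10, 30)); far <- rbind(c(50, 50, 50))
    if (t <= 5 || t == 11) near else far
  })
  tr <- scripted_system(20, pos)
  ions <- select_atoms(tr$topology, segment = "ion")
  m_open <- contact_map(tr, ions, frames = 0:9, partition_label = "open")
  m_closed <- contact_map(tr, ions, frames = 10:19,
                          partition_label = "closed")
  d <- contact_map_difference(m_open, m_closed)
  expect_equal(d$difference[d$residue_index == 1], 0.4)
})
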