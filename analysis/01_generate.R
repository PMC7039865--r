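#!/usr/bin/env Rscript
# Step 01: generate the synthetic study systems with known ground truth.
#
# Writes, under results/data/:
#   breathing_topology.pdb / breathing.dcd   100-frame breathing channel
#   gated_topology.pdb / gated.dcd           10-frame two-ended gated channel
#   membrane_ions.pdb                        leaflet markers + ion topology
#   ion_truth.tsv                            scripted ion ground-truth table

library(ionpath)
source("analysis/00_parameters.R")

cat("== generating synthetic study systems ==\n")

breathing <- make_channel_trajectory(
  channel_spec(N_SLICES, SLICE_SPACING, ATOMS_PER_RING, breathing_radius,
               seed = SEED), N_FRAMES_BREATHING)
write_trajectory(ip_trajectory(breathing$topology, breathing$frames[1]),
                 "results/data/breathing_topology.pdb")
write_trajectory(breathing, "results/data/breathing.dcd")
cat(sprintf("breathing channel: %d frames x %d atoms (true open frames: odd)\n",
            n_frames(breathing), nrow(breathing$topology$atoms)))

gated <- make_channel_trajectory(
  channel_spec(N_SLICES, SLICE_SPACING, ATOMS_PER_RING, gated_radius,
               seed = SEED + 1L), N_FRAMES_GATED)
write_trajectory(ip_trajectory(gated$topology, gated$frames[1]),
                 "results/data/gated_topology.pdb")
write_trajectory(gated, "results/data/gated.dcd")
cat(sprintf("gated channel: %d frames; frames open at both ends: %s\n",
            n_frames(gated), paste(OPEN_FRAMES, collapse = ", ")))

# membrane markers plus one scripted chloride (enters the membrane slab
# through the pore axis), one free chloride and three potassium controls
mk <- make_membrane_markers(Z_LOWER_LEAFLET, Z_UPPER_LEAFLET,
                            N_P_PER_LEAFLET, seed = SEED + 2L)
n_fr <- 30L
zpath <- seq(50, 80, length.out = n_fr)
wp <- data.frame(ion = 1L, frame = 0:(n_fr - 1L), x = 0, y = 0, z = zpath)
cl_ions <- make_ion_tracks(ion_spec(2, 0.8, seed = SEED + 3L,
                                    reflecting_box = c(60, 60, 55),
                                    waypoints = wp), n_fr)
k_ions <- make_ion_tracks(ion_spec(3, 1.0, seed = SEED + 4L,
                                   species = "POT",
                                   reflecting_box = c(60, 60, 50)), n_fr)
lip <- ip_trajectory(mk$topology, lapply(0:(n_fr - 1L), function(i)
  ip_frame(mk$frame$coords, i)))
membrane_system <- merge_trajectories(merge_trajectories(lip,
                                                         cl_ions$trajectory),
                                      k_ions$trajectory)
write_trajectory(membrane_system, "results/data/membrane_ions.pdb")
truth <- rbind(transform(cl_ions$truth, species = "CLA"),
               transform(k_ions$truth, species = "POT"))
write_tsv_report(truth, "results/data/ion_truth.tsv",
                 c("scripted ion ground truth (positions in A, 0-based frames)",
                   sprintf("chloride #1 scripted along z = 50..80; seeds %d..%d",
                           SEED + 3L, SEED + 4L)))
cat(sprintf("membrane system: %d atoms x %d frames; truth table %d rows\n",
            nrow(membrane_system$topology$atoms), n_fr, nrow(truth)))
cat("done.\n")
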