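# Shared study parameters for the analysis workflow.
# All lengths in Angstrom; frame indices 0-based; seeds fixed for
# reproducibility (change SEED to rerun the whole workflow on new draws).

SEED <- 20260928L

# synthetic channel geometry (TM-like pore in a slab)
N_SLICES <- 16L
SLICE_SPACING <- 1.5
ATOMS_PER_RING <- 16L

# breathing channel screened in step 02: minimum slab radius alternates
# 1.7 A (even frames, closed) / 2.2 A (odd frames, open)
N_FRAMES_BREATHING <- 100L
breathing_radius <- function(z, fr) {
  base <- 2.2 + 0.4 * abs(z - 11.25) / 11.25
  base - if (fr %% 2 == 0) 0.5 else 0
}

# gated channel searched in step 03: frames 2, 5, 9 open at both ends,
# all others blocked by a 1.2 A constriction at the extracellular end
N_FRAMES_GATED <- 10L
OPEN_FRAMES <- c(2L, 5L, 9L)
gated_radius <- function(z, fr) {
  if (fr %in% OPEN_FRAMES) return(rep(3, length(z)))
  ifelse(z > 19, 1.2, 3)
}

# screening thresholds (chloride radius criterion and Caver-style stage 2)
R_MIN <- 1.8
CUTOFF_RADIUS <- 1.8
SHELL_RADIUS <- 6
SHELL_DEPTH <- 3
CLUSTER_THRESHOLD <- 4.5
CONTACT_DISTANCE <- 3.0
ION_CONTACT_CUT <- 4.0
GRID_STEP <- 0.8

# membrane + ion tracks for step 05
Z_LOWER_LEAFLET <- 60
Z_UPPER_LEAFLET <- 100
N_P_PER_LEAFLET <- 60L

# correlated-motion design for step 06: residues 1..11 share one
# high-correlation block; 12..21 move independently
N_RESIDUES <- 21L
N_FRAMES_CORR <- 2000L
BLOCK_RESIDUES <- 1:11
BLOCK_RHO <- 0.9
NETWORK_CONTACT_CUT <- 8     # links 2nd chain neighbours -> parallel routes
PATH_TOLERANCE <- 1

# well-tempered metadynamics budget for step 07
METAD_STEPS <- 6e5
METAD_STRIDE <- 300L
METAD_H0 <- 1.2
METAD_SIGMA <- 0.35
METAD_GAMMA <- 10
METAD_TEMP <- 300

dir.create("results", showWarnings = FALSE)
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
dir.create("scratch", showWarnings = FALSE)   # binary caches between steps
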