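---
title: "Detecting and characterising ion-permeation pathways with ionpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterising ion-permeation pathways with ionpath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model

ionpath analyses molecular-dynamics trajectories of membrane-embedded ion
channels.  The central question is geometric: in which frames does the
protein enclose a continuous cavity wide enough for an ion to pass from the
intracellular to the extracellular side, where does that pathway run, which
residues line it, and how strongly is its gate coupled to remote regions of
the protein?  The package implements the full chain of analyses as testable
functions, and ships a synthetic-trajectory generator whose ground truth is
analytic, so every stage can be validated without running molecular
dynamics.

Throughout, coordinates and thresholds are in Angstrom, the z axis is the
membrane normal, energies are in kJ/mol and temperatures in Kelvin.  Frame
indices are 0-based internally and 1-based in printed output.

## Stage 1: pore profiling (`profile_pore`, `classify_open`)

For every frame, the pore is characterised by the maximal inscribed sphere
per z slice: at height $z$ the in-plane centre $c$ maximises

$$ r(c) = \min_i \left( \lVert c - a_i \rVert - \mathrm{vdw}_i \right), $$

the clearance against all pore-bounding atoms $a_i$ with van der Waals
radii $\mathrm{vdw}_i$ (Bondi-style table, overridable via `vdw_radii()`).
The transmembrane slab is the z interval between the centres of mass of two
Calpha anchor groups placed at the levels of the two lipid head-group
layers (`compute_slab()`); anchor selections are user configuration because
residue numbering differs between constructs and orthologs.  A frame is
**open** when every slab slice radius strictly exceeds `r_min = 1.8` — the
chloride ionic radius; the strict inequality means a pore of exactly 1.8
is closed.

Numerical choices.  The per-slice maximisation uses Nelder-Mead restarted
from the previous slice's optimum plus four deterministically jittered
starts (offsets of 0.75 along the in-plane axes), sweeping outward from the
slice nearest the seed point; this follows the pore as it meanders without
global search.  Slices default to 0.5 spacing.  Radii are capped at
`r_cap = 10`: a slice reaching the cap has merged with bulk solvent and is
flagged unbounded.  Only protein atoms bound the pore by default;
`include_lipids = TRUE` adds lipid atoms, which matters when acyl chains
intrude into the pathway — this intentionally changes the verdicts.  The
optimiser is validated against a brute-force 0.05-A in-plane grid scan and
agrees within 0.05 A on ring-channel geometries whose true radius is known
exactly.

## Stage 2: tunnel search (`search_tunnels`)

The slab criterion is necessary but not sufficient: a frame can be open in
the slab yet blocked above or below it, or open only towards the membrane.
Stage 2 therefore searches curved tunnels from an interior seed (the
Calpha midpoint of a configured residue pair, `seed_point()`) to the
protein surface, on a regular grid (default step 0.8) over the selected
transmembrane residues:

* nodes with clearance below `cutoff_radius = 1.8` are blocked;
* nodes with clearance at or above `shell_radius = 6` are bulk solvent;
* the exit layer is the set of admissible non-bulk nodes within
  `shell_depth = 3` of bulk (the molecular-surface boundary eroded inward,
  computed by constrained dilation of the bulk mask);
* edges connect 26-neighbour admissible nodes with the throughput cost
  $\text{len}/r_\text{mid}^2$, where $r_\text{mid}$ is the clearance at
  the edge midpoint, evaluated exactly; edges whose midpoint clearance
  falls below the cutoff are removed, so a path cannot thread a
  sub-cutoff constriction between two admissible nodes;
* lowest-cost paths from the seed to exit nodes are computed by Dijkstra's
  algorithm (via igraph), and **each path is truncated at its first exit
  node**: a tunnel ends at its first surface contact and may not re-enter
  and continue elsewhere.  Without this rule a path could circle the
  protein inside the 1.8–6 A clearance sheath and misreport a blocked end
  as open.

The cost formula is the one design point the method leaves open: "tunnel
cost" is only parameterised, not defined, in the tools this pipeline
mirrors.  The length-over-radius-squared form is the standard
throughput-style choice and is isolated behind the edge-construction
function; on the validation cavities it reproduces the analytic per-length
costs $1/r^2$ of straight branches and ranks a wide 10-A branch (cost
$\approx 10/9$) ahead of a narrow 6-A branch (cost $\approx 6/4$).

Distinct tunnels are formed by grouping paths whose symmetrised mean
closest-point divergence is below the 4.5-A clustering threshold, walking
candidates in increasing cost order (each group's representative is its
cheapest member).  Exit candidates are pre-thinned by the same threshold on
endpoint spacing — cheapest first — so only one candidate per surface patch
is expanded.  Endpoints classify as intracellular (final sphere below the
slab), extracellular (above), or lateral (inside the slab; the
membrane-facing fenestration case), and lateral tunnels are excluded from
pairing.  A frame is an **open conformation** when it has at least one
intracellular and one extracellular tunnel; the selected pair minimises
summed cost, with ties broken towards the larger combined bottleneck and
then the lower tunnel index.

Accuracy is bounded by the grid step: bottleneck radii on synthetic
cylinders are exact to within one step.  The grid search trades the exact
Voronoi construction of the original tunnel tools for oracle-checkable
simplicity; shortest-path optimality is verified against an independent
Dijkstra implementation on the full grid graph.

## Channel statistics

A residue **lines** a tunnel when any of its (heavy) atoms is within 3.0 A
of a tunnel sphere *surface* (gap = centre distance minus sphere radius,
strict `<`).  `lining_frequency()` counts, per residue, the open frames in
which it lines the selected pair, normalised by the maximum count so the
plot peaks at 1; normalising by the number of open frames is available via
`normalize = "n_open"` since either denominator is defensible and the
choice only rescales the axis.

`cluster_channels()` compares open frames by the RMSD over the atoms of
the **union** of their lining-residue sets (all atoms exist in all frames;
only the lining label differs, so the union needs no imputation) and
applies Ward agglomeration (`hclust`, `ward.D2`), cut at the 4.5-A
threshold by default.  The merge order is validated against a naive
Lance-Williams implementation.  Frames are assumed pre-aligned
(`align_trajectory()`).

`radius_profile_z()` pools the spheres of every selected pair and averages
radii in 1-A z bins (the bin width is a display choice; the underlying
sphere pool is exposed through the per-bin counts).

## Ion contacts

`contact_map()` counts a (residue, ion) pair once per frame when any atom
of the residue is strictly within 4.0 A of the ion, with minimum-image
distances when a box is present.  The per-residue frequency is the
fraction of partition frames with any-ion contact, which makes open and
closed partitions directly comparable; `contact_map_difference()`
differences these per-frame rates.  Counting at residue level per frame
(rather than atom pairs) matches the "contact of each amino acid"
semantics and makes counts additive across frame partitions — a property
the tests assert exactly on waypoint-scripted tracks.

`ion_z_tracks()` records each ion's z against the per-frame leaflet
boundaries (centre of mass of the phosphorus markers of each leaflet,
split at the marker z median).  An ion has *entered* when its z lies
between the leaflet centres **and** its lateral distance to the pore axis
is under 15 A; the lateral envelope is a documented stand-in for "inside
the protein", which the source analyses leave unquantified, and it is
configurable.

## Dynamical network analysis

`correlation_matrix()` computes the dynamical cross-correlation of Calpha
displacement vectors over a frame window,
$C_{ij} = \langle \Delta r_i \cdot \Delta r_j \rangle /
\sqrt{\langle |\Delta r_i|^2 \rangle \langle |\Delta r_j|^2 \rangle}$,
after superposing each frame onto the window mean (two fit iterations)
so rigid-body motion does not read as correlation.  Residues immobile
after fitting get zero correlations and a warning.  The synthetic
block-motion generator produces no rigid-body component, so its recovery
tests use `fit = FALSE`; with fitting enabled the superposition absorbs
part of the block signal on short chains, which is expected behaviour,
not an estimator defect.

`build_network()` keeps edges between residues whose heavy atoms come
within 4.5 A in at least 75% of window frames (consecutive residues
included) and weights them $w_{ij} = -\ln |C_{ij}|$; anti-correlated
motion counts as coupling.  `suboptimal_paths()` enumerates **exactly**
all simple paths within `tolerance` of the optimal path length, by
depth-first search pruned with the admissible best-remaining-distance
bound from a reverse Dijkstra pass; exactness is verified against
brute-force enumeration on graphs of up to 12 nodes.  Weights are kept as
real numbers with a user-set tolerance rather than the integer-scaled
convention of the original path-enumeration tools — same semantics,
clearer units.  Because the tolerance is an absolute quantity in
$-\ln|C|$ units, counts are comparable only within one run and across
equal-hop routes; the packaged validation therefore contrasts two sources
at the same hop distance from one sink, one routed through a correlated
block and one through independent residues, and asserts the designed
ranking rather than absolute counts.

## Well-tempered metadynamics

The engine biases the distance CV $s = |r_\text{ion} - r_\text{COM}|$
(unit-mass COM over fixed anchors — mass weighting is immaterial for
Calpha-only anchor groups) with Gaussian hills deposited every `stride`
steps.  Hill heights follow the well-tempered rule
$h_t = h_0 \exp(-V(s_t)/k_B \Delta T)$ with $\Delta T = (\gamma - 1) T$;
the defaults $h_0 = 1.2$ kJ/mol, $\sigma = 0.35$ A, stride 500,
$\gamma = 10$ are conventional values (the source analyses do not state
theirs) and all are configurable.  The bias and its derivative are cached
on a fine grid, PLUMED-style, so evaluation is O(1) per step.

Restraints: half-harmonic CV walls ($k(s - b)^2$ outside $[5, 20]$ by
default) and a three-point angle restraint with the vertex at the
extracellular-leaflet phosphorus COM, penalising angles above 80 degrees.
The point ordering admits two vertex readings; the first-listed point is
the default vertex and `vertex = "B"` selects the other.  All restraint
forces are analytic gradients, checked against finite differences to
1e-5.

Sampling uses overdamped Langevin dynamics,
$\Delta x = (F/\gamma_f)\,\Delta t + \sqrt{2 k_B T \Delta t/\gamma_f}\,\xi$,
on analytic potentials; the integrator reproduces the Einstein relation on
a flat potential and the Boltzmann distribution in a harmonic well.  Only
the ion moves; anchors and leaflet centres are fixed — the toy geometry
isolates the bias logic, which is the part under test.

The 1D profile is reconstructed as
$F(s) = -\frac{T + \Delta T}{\Delta T} V(s)$ (minimum shifted to zero).
2D projections onto component pairs of the separation vector are built by
reweighted histograms with final-bias weights $e^{V(s_t)/k_B T}$, because
the bias acts on the 1D distance — depositing 2D hills would be a
different method.  On a radial double well with a 5-$k_B T$ barrier the
reconstructed barrier agrees with the numerically exact Boltzmann marginal
$F(s) = U(s) - 2 k_B T \ln s$ within a few percent at the default budget
(6×10^5 steps, hills every 300 steps), comfortably inside the 20% band
the validation asserts; note the $-2 k_B T \ln s$ Jacobian term, which a
naive comparison against $U(s)$ alone would miss.

## The synthetic generator: what it does and does not emulate

The generator builds the study systems from which every ground truth
follows analytically:

* **Channel** (`make_channel_trajectory`): rings of pseudo-atoms centred
  on the z axis, ring radius = target pore radius + atom vdW radius, so
  the true inscribed radius per slice *is* the requested profile.  The
  breathing screen uses 100 frames of a 16-ring channel whose minimum slab
  radius alternates 1.7/2.2 A; the gating study uses 10 frames with a
  1.2-A extracellular constriction on all but frames 2, 5 and 9.
* **Membrane** (`make_membrane_markers`): phosphorus-like markers with
  leaflet centres recentred exactly at the requested heights.
* **Ions** (`make_ion_tracks`): reflecting Gaussian random walks with
  optional deterministic waypoints, so contact counts are known exactly
  from the script rather than from physics.
* **Correlated motions** (`make_correlated_trajectory`): a 3.8-A Calpha
  chain with per-frame displacements from the shared-factor construction
  $\sqrt{\rho}\,Z_b + \sqrt{1 - \rho}\,E_i$, giving exact block
  correlation $\rho$.

What passing these tests shows: the geometry, counting, graph and bias
machinery is correct against known truth.  What it does not show: realism
of protein energetics, solvent, membrane deformation, or conformational
kinetics — no force field is involved, ions do not interact with the
channel walls, and the channel "breathes" by construction rather than by
dynamics.  Conclusions about real channels still require real
trajectories; this package guarantees the analysis of such trajectories is
computed correctly.

## Problem sizes and determinism

The packaged validation runs at desk scale, chosen so the whole suite
completes in minutes on one core: 100-frame screens of 256-atom channels,
10-frame tunnel searches on 0.8-A grids, 2000-frame correlation windows
over 21 residues, 6×10^5-step metadynamics runs, and oracle comparisons
(0.05-A grid scans, full-graph Dijkstra, exhaustive path enumeration,
naive Ward agglomeration) on correspondingly small instances.  Every
random draw flows through one seeded generator (`with_seed`), so all
results are bit-reproducible; generator functions restore the caller's RNG
state.

## Known limitations

* The grid tunnel search bounds accuracy by the grid step and is not a
  Voronoi construction; very narrow side channels just above the cutoff
  may be missed between grid planes.
* The exit layer operationalises "molecular surface eroded by the shell
  depth" via clearance thresholds and constrained dilation; shell
  semantics of the original tunnel tools are only approximated.
* Suboptimal-path counts depend on the absolute tolerance; cross-run
  comparisons require a fixed tolerance and comparable path lengths.
* The 2D FES projections are reweighted from a 1D bias and inherit its
  convergence; deep features orthogonal to the distance CV are not
  accelerated.
* bio3d's PDB writer mis-aligns 4-character residue names, so trajectories
  are written with names truncated to the standard 3-column field; DCD
  output avoids the issue entirely.
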