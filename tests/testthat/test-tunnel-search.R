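test_that("the search seed is the midpoint of two Calpha atoms", {
  topo <- fix_point_topology(matrix(0, 2, 3))
  fr <- ip_frame(rbind(c(0, 0, 70), c(0, 0, 90)))
  expect_equal(seed_point(fr, topo, c(1, 2)), c(0, 0, 80))
  fr2 <- ip_frame(rbind(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(seed_point(fr2, topo, c(1, 2)), c(1, 2, 3))
  topo2 <- fix_point_topology(matrix(0, 2, 3), atom_name = "CB")
  expect_error(seed_point(fr, topo2, c(1, 2)), class = "selection_error")
})

test_that("a straight cylinder gives one tunnel family per end on the axis", {
  tr <- fix_channel(function(z, fr) 3.0, n_slices = 16, apr = 16)
  slab <- fix_slab(tr)
  tun <- search_tunnels(tr$frames[[1]], tr$topology,
                        seed = c(0, 0, 11.25), grid_step = 0.8)
  tun <- lapply(tun, classify_endpoint, slab = slab)
  ends <- vapply(tun, `[[`, character(1), "endpoint")
  expect_equal(sort(ends[ends != "lateral"]),
               c("extracellular", "intracellular"))
  axial <- tun[ends != "lateral"]
  for (t in axial) {
    expect_equal(t$bottleneck_radius, 3.0, tolerance = 0.8)  # grid_step
    in_chan <- t$spheres$z > 0 & t$spheres$z < 22.5
    expect_true(all(sqrt(t$spheres$x[in_chan]^2 + t$spheres$y[in_chan]^2)
                    <= 0.8 * sqrt(3) + 1e-9))
  }
})

test_that("a sub-cutoff constriction blocks passage", {
  profile <- function(z, fr) ifelse(abs(z - 12) < 0.1, 1.7, 3.0)
  tr <- fix_channel(profile, n_slices = 16, apr = 16)
  slab <- fix_slab(tr)
  # seed below the constriction: no extracellular route may exist
  tun <- search_tunnels(tr$frames[[1]], tr$topology, seed = c(0, 0, 6),
                        grid_step = 0.8)
  tun <- lapply(tun, classify_endpoint, slab = slab)
  ends <- vapply(tun, `[[`, character(1), "endpoint")
  expect_false("extracellular" %in% ends)
  expect_true("intracellular" %in% ends)
})

test_that("branch costs follow length / radius^2 and rank accordingly", {
  # branch A: length ~10 above the seed, radius 3 (cost ~10/9);
  # branch B: length ~6 below, radius 2 (cost ~6/4) -> A ranks first
  profile <- function(z, fr) ifelse(z >= 6, 3.0, 2.0)
  tr <- fix_channel(profile, n_slices = 12, spacing = 1.5, apr = 16)
  slab <- fix_slab(tr)
  tun <- search_tunnels(tr$frames[[1]], tr$topology, seed = c(0, 0, 6.75),
                        grid_step = 0.75)
  tun <- lapply(tun, classify_endpoint, slab = slab)
  ends <- vapply(tun, `[[`, character(1), "endpoint")
  up <- tun[[match("extracellular", ends)]]
  dn <- tun[[match("intracellular", ends)]]
  expect_lt(up$cost, dn$cost)
  # per-length cost approximates 1/r^2 of each branch
  expect_equal(up$cost / up$length, 1 / 9, tolerance = 0.35)
  expect_equal(dn$cost / dn$length, 1 / 4, tolerance = 0.35)
})

test_that("tunnel costs equal an independent Dijkstra over the full grid graph", {
  tr <- fix_channel(function(z, fr) 2.6, n_slices = 8, spacing = 1.5,
                    apr = 12)
  tun <- search_tunnels(tr$frames[[1]], tr$topology, seed = c(0, 0, 5.25),
                        grid_step = 1.0, keep_grid = TRUE)
  g <- attr(tun, "grid")
  dist <- ref_dijkstra(sum(g$interior), g$edges, g$seed_node)
  for (t in tun) {
    # end node of the representative path
    last <- t$spheres[nrow(t$spheres), ]
    end_id <- which(abs(g$node_xyz[, 1] - last$x) < 1e-9 &
                    abs(g$node_xyz[, 2] - last$y) < 1e-9 &
                    abs(g$node_xyz[, 3] - last$z) < 1e-9)
    expect_equal(t$cost, dist[end_id], tolerance = 1e-9)
  }
})

test_that("reported spheres always satisfy the cutoff clearance", {
  tr <- fix_channel(function(z, fr) 2.2 + 0.04 * z, n_slices = 12, apr = 16)
  tun <- search_tunnels(tr$frames[[1]], tr$topology, seed = c(0, 0, 8),
                        grid_step = 0.8)
  prot <- select_atoms(tr$topology, segment = "protein")
  axyz <- tr$frames[[1]]$coords[prot, ]
  avdw <- tr$topology$atoms$vdw_radius[prot]
  for (t in tun) {
    cl <- ionpath:::clearance_points(
      as.matrix(t$spheres[, c("x", "y", "z")]), axyz, avdw)
    expect_true(all(cl >= 1.8 - 1e-9))
    expect_equal(t$bottleneck_radius, min(t$spheres$radius))
  }
})

test_that("endpoint classification splits at the slab boundaries", {
  slab <- membrane_slab(61, 100)
  mk <- function(z_end) fix_tunnel(cbind(0, 0, c(80, z_end)), c(2, 2))
  expect_equal(classify_endpoint(mk(40), slab)$endpoint, "intracellular")
  expect_equal(classify_endpoint(mk(110), slab)$endpoint, "extracellular")
  expect_equal(classify_endpoint(mk(80), slab)$endpoint, "lateral")
  one <- fix_tunnel(cbind(0, 0, 80), 2)
  expect_error(classify_endpoint(one, slab), class = "input_error")
})

test_that("open conformations need both ends and pick the cheapest pair", {
  slab <- membrane_slab(10, 20)
  ic_cheap <- fix_tunnel(cbind(0, 0, c(15, 5)), c(3, 3))     # cost 10/9
  ic_dear <- fix_tunnel(cbind(0, 0, c(15, 5)), c(2, 2))      # cost 10/4
  ec <- fix_tunnel(cbind(0, 0, c(15, 25)), c(2.5, 2.5))
  lateral <- fix_tunnel(cbind(0, c(0, 8), c(15, 15)), c(2, 2))
  sets <- list(list(ic_cheap, ic_dear, ec),    # frame 0: open
               list(ic_cheap, ic_dear),        # frame 1: IC only
               list(ec, lateral))              # frame 2: EC only
  sets[[2]] <- lapply(sets[[2]], function(t) { t$frame_index <- 1L; t })
  sets[[3]] <- lapply(sets[[3]], function(t) { t$frame_index <- 2L; t })
  open <- select_open_conformations(sets, slab)
  expect_length(open, 1)
  expect_equal(open[[1]]$frame_index, 0L)
  expect_equal(unname(open[[1]]$pair), c(1L, 3L))   # cheapest IC + the EC
})

test_that("ties in pair cost break towards the larger combined bottleneck", {
  slab <- membrane_slab(10, 20)
  ic_a <- fix_tunnel(cbind(0, 0, c(15, 5)), c(2, 2))         # cost 2.5
  ic_b <- fix_tunnel(cbind(0, 0, c(15, 10 - 1e-9, 5)), c(2, 2, 2))
  ic_b$cost <- ic_a$cost                                     # forced tie
  ic_b$bottleneck_radius <- 3                                # but wider
  ic_b$spheres$radius <- 3
  ec <- fix_tunnel(cbind(0, 0, c(15, 25)), c(2, 2))
  open <- select_open_conformations(list(list(ic_a, ic_b, ec)), slab)
  expect_equal(unname(open[[1]]$pair[1]), 2L)
})
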