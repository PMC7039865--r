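test_that("correlation matrix is symmetric, bounded and unit-diagonal", {
  tr <- make_correlated_trajectory(correlated_motion_spec(
    15, 400, list(list(residues = 1:5, rho = 0.7)), seed = 31))
  C <- correlation_matrix(tr, fit = FALSE)
  expect_equal(C, t(C), tolerance = 1e-10)
  expect_true(all(abs(C) <= 1 + 1e-10))
  expect_equal(unname(diag(C)), rep(1, 15))
})

test_that("rigid global translation is removed by fitting and flagged immobile", {
  base <- cbind(3.8 * (0:9), 0, 0)
  frames <- lapply(0:49, function(i)
    ip_frame(base + matrix(rnorm(3), 10, 3, byrow = TRUE), i))
  tr <- ip_trajectory(fix_point_topology(base), frames)
  expect_warning(C <- correlation_matrix(tr, fit = TRUE), "immobile")
  expect_true(all(C[upper.tri(C)] == 0))
})

test_that("edge weights are -ln|C| with anti-correlation counting as coupling", {
  net <- network_from_edges(data.frame(i = c(1, 2, 3), j = c(2, 3, 4),
                                       correlation = c(1, -1, exp(-1))))
  expect_equal(net$edges$weight, c(0, 0, 1))
  expect_error(network_from_edges(data.frame(i = 1, j = 2, weight = -0.1)),
               class = "input_error")
})

test_that("the contact filter keeps chain neighbours and drops distant pairs", {
  tr <- make_correlated_trajectory(correlated_motion_spec(
    8, 60, list(), noise_sigma = 0.1, seed = 5))
  C <- correlation_matrix(tr, fit = FALSE)
  net <- build_network(C, tr, contact_cut = 4.5, contact_fraction = 0.75)
  pairs <- paste(net$edges$i, net$edges$j)
  expect_setequal(pairs, paste(1:7, 2:8))    # 3.8 A chain: only neighbours
})

test_that("path enumeration matches simple closed-form graphs", {
  chain <- network_from_edges(data.frame(i = 1:3, j = 2:4, weight = 1))
  pe <- suboptimal_paths(chain, 1, 4, tolerance = 1.9)
  expect_equal(pe$count, 1L)
  expect_equal(pe$optimal_path, 1:4)
  expect_equal(pe$optimal_length, 3)
  # 6-node graph with two equal-cost routes
  twin <- network_from_edges(data.frame(
    i = c(1, 2, 3, 1, 5, 6), j = c(2, 3, 4, 5, 6, 4), weight = 1))
  pe2 <- suboptimal_paths(twin, 1, 4, tolerance = 0)
  expect_equal(pe2$count, 2L)
  # self path
  pe3 <- suboptimal_paths(chain, 2, 2, tolerance = 0)
  expect_equal(pe3$count, 1L)
  expect_equal(pe3$optimal_length, 0)
  # disconnected pair
  iso <- network_from_edges(data.frame(i = c(1, 3), j = c(2, 4), weight = 1))
  pe4 <- suboptimal_paths(iso, 1, 4, tolerance = 10)
  expect_equal(pe4$count, 0L)
})

test_that("enumeration equals the brute-force oracle on random graphs", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(6:12, 1)
    # random connected-ish graph
    edges <- data.frame(i = 1:(n - 1), j = 2:n,
                        weight = runif(n - 1, 0.2, 1.5))
    extra <- t(combn(n, 2))
    extra <- extra[sample(nrow(extra), min(n, nrow(extra))), , drop = FALSE]
    edges <- unique(rbind(edges,
                          data.frame(i = extra[, 1], j = extra[, 2],
                                     weight = runif(nrow(extra), 0.2, 1.5))))
    edges <- edges[!duplicated(paste(pmin(edges$i, edges$j),
                                     pmax(edges$i, edges$j))), ]
    net <- network_from_edges(edges)
    tol <- runif(1, 0, 2)
    pe <- suboptimal_paths(net, 1, n, tolerance = tol)
    budget <- pe$optimal_length + tol
    expect_equal(pe$count,
                 ref_paths_within(net$graph, "1", as.character(n), budget))
    # every returned path is simple and within budget; optimal is a member
    expect_true(all(vapply(pe$paths, anyDuplicated, integer(1)) == 0))
    expect_true(all(pe$lengths <= budget + 1e-9))
    expect_true(all(pe$lengths >= pe$optimal_length - 1e-9))
  }
})

test_that("the suboptimal count is non-decreasing in tolerance", {
  set.seed(17)
  edges <- data.frame(i = rep(1:6, each = 2),
                      j = c(2, 3, 3, 4, 4, 5, 5, 6, 6, 7, 7, 7),
                      weight = runif(12, 0.1, 1))
  edges <- edges[edges$i < edges$j, ]
  net <- network_from_edges(unique(edges))
  counts <- vapply(c(0, 0.2, 0.5, 1, 2, 4), function(tol)
    suboptimal_paths(net, 1, 7, tol)$count, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("a correlated route yields more suboptimal paths than an uncorrelated one", {
  # two sources at the same hop distance from one sink; the route from
  # source A runs through a high-correlation block (cheap edges, many
  # near-optimal detours), the route from source B through independent
  # residues (expensive edges, few alternatives within the same tolerance)
  spec <- correlated_motion_spec(
    21, 1200, list(list(residues = 1:11, rho = 0.95)),
    noise_sigma = 0.15, seed = 41)
  tr <- make_correlated_trajectory(spec)
  C <- correlation_matrix(tr, fit = FALSE)
  # a wider contact cutoff links second neighbours along the chain, so
  # alternative routes exist and path counts can discriminate coupling
  net <- build_network(C, tr, contact_cut = 8)
  tol <- 1
  strong <- suboptimal_paths(net, 1, 11, tolerance = tol)$count
  weak <- suboptimal_paths(net, 21, 11, tolerance = tol)$count
  expect_gt(strong, weak)
  # and the coupling table ranks the correlated source first
  tab <- coupling_table(net, sources = c(1, 21), sinks = 11,
                        tolerance = tol)
  expect_equal(tab$source[tab$rank == 1], 1)
})

test_that("the coupling table covers all source-sink combinations", {
  net <- network_from_edges(data.frame(i = 1:7, j = 2:8, weight = 0.3))
  tab <- coupling_table(net, sources = c(1, 2, 3, 4), sinks = c(7, 8),
                        tolerance = 0.5)
  expect_equal(nrow(tab), 8)
  expect_true(all(tab$count >= 1))
  expect_error(coupling_table(net, 1:2, integer(0)), class = "input_error")
})
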