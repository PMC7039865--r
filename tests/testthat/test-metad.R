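kB <- 0.00831446261815324

test_that("the distance CV returns the separation vector and its norm", {
  expect_equal(cv_value(c(3, 4, 0), matrix(0, 1, 3))$s, 5)
  expect_equal(cv_value(c(3, 4, 0), matrix(0, 1, 3))$components, c(3, 4, 0))
  expect_equal(cv_value(c(1, 1, 1), matrix(1, 4, 3))$s, 0)
  anchors <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  got <- cv_value(c(0, 0, 7), anchors)
  expect_equal(got$s, 7)
  expect_equal(got$grad, c(0, 0, 1))
  expect_error(cv_value(c(0, 0, 0), matrix(0, 0, 3)),
               class = "selection_error")
})

test_that("bias accumulation follows the closed-form Gaussian sum", {
  bs <- bias_state(h0 = 1, sigma = 1, bias_factor = 5, temperature = 300,
                   grid_min = 0, grid_max = 20, grid_n = 4001)
  expect_equal(bias_energy(bs, 7.3), 0)
  bs <- deposit_hill(bs, 10)
  expect_equal(bs$hills$height[1], 1)               # first hill = h0
  expect_equal(bias_energy(bs, 10), 1, tolerance = 1e-4)
  expect_equal(bias_energy(bs, 11), exp(-0.5), tolerance = 1e-4)
  # grid derivative equals the analytic hill derivative
  s_chk <- 10.7
  expect_equal(bias_derivative(bs, s_chk),
               -exp(-(s_chk - 10)^2 / 2) * (s_chk - 10), tolerance = 1e-3)
  expect_error(bias_state(bias_factor = 1), class = "parameter_error")
})

test_that("hill heights decay monotonically under repeated visits", {
  bs <- bias_state(h0 = 1.2, sigma = 0.35, bias_factor = 10,
                   temperature = 300, grid_min = 0, grid_max = 20)
  for (k in 1:1000) bs <- deposit_hill(bs, 10)
  h <- bs$hills$height
  expect_true(all(diff(h) < 0))
  expect_lt(h[1000], h[1] / 20)
})

test_that("wall energies use the stated half-harmonic convention", {
  w <- wall_restraint(lower = 5, upper = 20, force_constant = 10)
  anchors <- matrix(0, 1, 3)
  expect_equal(restraint_energy(c(12, 0, 0), anchors, wall = w)$energy, 0)
  expect_equal(restraint_energy(c(22, 0, 0), anchors, wall = w)$energy, 40)
  expect_equal(restraint_energy(c(0, 3, 0), anchors, wall = w)$energy, 40)
  expect_error(wall_restraint(20, 5), class = "parameter_error")
})

test_that("the angle restraint penalises only beyond the threshold", {
  A <- c(0, 0, 100); B <- c(0, 0, 60)    # EC leaflet COM, IC leaflet COM
  ar <- angle_restraint(A, B, max_angle = 80, force_constant = 100)
  # ion straight below A: angle ~0
  expect_equal(restraint_energy(c(0, 0, 80), matrix(0, 1, 3),
                                angle = ar)$energy, 0)
  # ion to the side of A at 90 degrees from the A->B ray
  e90 <- restraint_energy(c(30, 0, 100), matrix(0, 1, 3), angle = ar)
  expect_gt(e90$energy, 0)
  expect_error(restraint_energy(A, matrix(0, 1, 3),
                                angle = angle_restraint(A, A)),
               class = "geometry_error")
  # vertex choice is configurable
  ar_b <- angle_restraint(A, B, vertex = "B")
  expect_equal(restraint_energy(c(0, 0, 80), matrix(0, 1, 3),
                                angle = ar_b)$energy, 0)
})

test_that("restraint forces match numerical gradients", {
  anchors <- rbind(c(1, 2, 3), c(-1, 0, 1), c(0, 1, -2), c(2, -1, 0))
  w <- wall_restraint(2, 6, force_constant = 7)
  ar <- angle_restraint(c(0, 0, 10), c(0, 0, -10), max_angle = 30,
                        force_constant = 50)
  for (pos in list(c(7, 1, 2), c(0.4, 0.2, 0.9), c(5, 5, 9))) {
    got <- restraint_energy(pos, anchors, wall = w, angle = ar)
    num <- vapply(1:3, function(k) {
      h <- 1e-6
      ep <- pos; em <- pos; ep[k] <- ep[k] + h; em[k] <- em[k] - h
      (restraint_energy(ep, anchors, wall = w, angle = ar)$energy -
         restraint_energy(em, anchors, wall = w, angle = ar)$energy) / (2 * h)
    }, numeric(1))
    scale <- max(1, sqrt(sum(num^2)))
    expect_equal(got$force / scale, -num / scale, tolerance = 1e-5)
  }
})

test_that("free diffusion follows the Einstein relation", {
  flat <- function(pos) list(energy = 0, force = c(0, 0, 0))
  run <- run_langevin_metad(flat, c(0, 0, 0), matrix(0, 1, 3),
                            n_steps = 1e5, dt = 0.002, friction = 1,
                            temperature = 300, seed = 3, record_stride = 10)
  D <- kB * 300 / 1                      # kT / friction
  # per-axis increment variance over record_stride steps = 2 D dt stride
  for (axis in c("x", "y", "z")) {
    v <- var(diff(run$samples[[axis]]))
    expect_equal(v, 2 * D * 0.002 * 10, tolerance = 0.1)
  }
})

test_that("an unbiased harmonic well samples the Boltzmann distribution", {
  k <- 4
  pot <- function(pos) list(energy = k * sum(pos^2), force = -2 * k * pos)
  run <- run_langevin_metad(pot, c(0, 0, 0), matrix(0, 1, 3),
                            n_steps = 2e5, dt = 0.002, friction = 1,
                            temperature = 300, seed = 5,
                            record_stride = 20)
  sd_exp <- sqrt(kB * 300 / (2 * k))
  x <- run$samples$x
  expect_lt(abs(mean(x)), 3 * sd_exp / sqrt(300))  # ~300 independent draws
  expect_equal(sd(x), sd_exp, tolerance = 0.1)
  # empirical CDF close to the Gaussian reference; thin to every 5th
  # recorded sample (100 integrator steps ~ 1.6 relaxation times, so the
  # retained draws are close to independent, n ~ 2000)
  xt <- x[seq(1, length(x), by = 5)]
  ks <- max(abs(stats::pnorm(sort(xt), 0, sd_exp) -
                  seq_along(xt) / length(xt)))
  expect_lt(ks, 0.05)
})

test_that("bias lets a double-well particle cross where unbiased dynamics stays", {
  T_low <- 120
  pot <- radial_double_well(c(0, 0, 0), 6, 10, barrier = 10 * kB * T_low)
  plain <- run_langevin_metad(pot, c(6, 0, 0), matrix(0, 1, 3),
                              n_steps = 8e4, dt = 0.002, friction = 1,
                              temperature = T_low, seed = 8)
  expect_lt(max(plain$samples$s), 8)     # trapped in the inner well
  bs <- bias_state(h0 = 1.5, sigma = 0.35, bias_factor = 10,
                   temperature = T_low, stride = 200,
                   grid_min = 0, grid_max = 16)
  biased <- run_langevin_metad(pot, c(6, 0, 0), matrix(0, 1, 3),
                               n_steps = 8e4, dt = 0.002, friction = 1,
                               temperature = T_low, bias = bs, seed = 8)
  expect_gt(max(biased$samples$s), 9)    # both wells visited
})

test_that("runs are bit-reproducible under a fixed seed", {
  pot <- radial_double_well(c(0, 0, 0), 6, 10, barrier = 10)
  bs <- bias_state(grid_min = 0, grid_max = 16, stride = 100)
  r1 <- run_langevin_metad(pot, c(6, 0, 0), matrix(0, 1, 3), 5000,
                           bias = bs, seed = 42)
  r2 <- run_langevin_metad(pot, c(6, 0, 0), matrix(0, 1, 3), 5000,
                           bias = bs, seed = 42)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$bias$hills, r2$bias$hills)
  expect_error(run_langevin_metad(pot, c(6, 0, 0), matrix(0, 1, 3), 100),
               class = "parameter_error")     # seed is mandatory
})

test_that("a single-hill FES is the mirrored, scaled Gaussian", {
  bs <- bias_state(h0 = 2, sigma = 0.5, bias_factor = 8, temperature = 300,
                   grid_min = 0, grid_max = 20, grid_n = 4001)
  bs <- deposit_hill(bs, 10)
  fes <- reconstruct_fes(bs, grid = seq(8, 12, by = 0.01))
  scale <- (300 + bs$delta_T) / bs$delta_T
  expected <- -scale * 2 * exp(-(fes$s - 10)^2 / (2 * 0.25))
  expected <- expected - min(expected)
  expect_equal(fes$F, expected, tolerance = 1e-3)
  expect_true(all(fes$F >= 0))
  expect_error(reconstruct_fes(bias_state()), class = "analysis_error")
})

test_that("2D projections put minima where the sampling dwells", {
  pot <- radial_double_well(c(0, 0, 0), 5, 9, barrier = 8)
  bs <- bias_state(h0 = 1.2, sigma = 0.35, bias_factor = 10,
                   temperature = 300, stride = 250, grid_min = 0,
                   grid_max = 14)
  run <- run_langevin_metad(pot, c(5, 0, 0), matrix(0, 1, 3), 1.2e5,
                            bias = bs, seed = 13)
  pr <- project_fes_2d(run$samples, run$bias, components = c("sx", "sz"),
                       bins = 40)
  expect_equal(dim(pr$F), c(40, 40))
  expect_equal(min(pr$F, na.rm = TRUE), 0)
  # low-F cells concentrate near radii 5 and 9 in the projected plane
  low <- which(pr$F < 2, arr.ind = TRUE)
  r_low <- sqrt(pr$a_mid[low[, 1]]^2 + pr$b_mid[low[, 2]]^2)
  expect_true(all(r_low > 3 & r_low < 11))
})
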