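# ---------------------------------------------------------------------------
# Self-contained well-tempered metadynamics engine.
#
# The collective variable (CV) is the distance between a mobile particle
# (the ion) and the centre of mass of a fixed anchor group; history-dependent
# Gaussian hills are deposited on the CV with well-tempered height damping,
# optional wall and angle restraints steer the particle, and overdamped
# Langevin dynamics on analytic potentials drives the sampling.  Energies
# are in kJ/mol, lengths in Angstrom, temperatures in Kelvin.
# ---------------------------------------------------------------------------

.kB <- 0.00831446261815324  # kJ/mol/K

#' Distance collective variable
#'
#' `s = |r_ion - r_COM|` with the centre of mass taken with unit masses over
#' the anchor group.
#'
#' @param positions ion position, length-3 numeric (A).
#' @param anchors n x 3 matrix of anchor coordinates (A), n >= 1.
#' @return list `s`, `components` (sx, sy, sz = r_ion - r_COM) and `grad`
#'   (d s / d r_ion, the unit separation vector; zero vector at s = 0).
#' @examples
#' cv_value(c(3, 4, 0), matrix(0, 1, 3))$s  # 5
#' @export
cv_value <- function(positions, anchors) {
  anchors <- as.matrix(anchors)
  if (!nrow(anchors)) stop_ip("selection_error", "empty anchor group")
  com <- colMeans(anchors)
  v <- as.numeric(positions) - com
  s <- sqrt(sum(v^2))
  list(s = s, components = v,
       grad = if (s > 1e-12) v / s else c(0, 0, 0))
}

#' Well-tempered bias state
#'
#' Holds the deposited Gaussian hills and a fine grid cache of the bias
#' potential and its derivative (PLUMED-style grids) for O(1) evaluation.
#'
#' @param h0 initial hill height (kJ/mol), default 1.2.
#' @param sigma hill width (A), default 0.35.
#' @param bias_factor well-tempered bias factor gamma (> 1), default 10.
#' @param temperature system temperature (K), default 300.
#' @param stride deposition stride in integrator steps, default 500.
#' @param grid_min,grid_max CV range covered by the grid (A).
#' @param grid_n number of grid points.
#' @return a `bias_state`.
#' @export
bias_state <- function(h0 = 1.2, sigma = 0.35, bias_factor = 10,
                       temperature = 300, stride = 500L,
                       grid_min = 0, grid_max = 30, grid_n = 2000L) {
  if (bias_factor <= 1)
    stop_ip("parameter_error", "bias_factor must be > 1")
  if (sigma <= 0 || h0 <= 0)
    stop_ip("parameter_error", "hill height and width must be > 0")
  structure(list(h0 = h0, sigma = sigma, bias_factor = bias_factor,
                 temperature = temperature, stride = as.integer(stride),
                 delta_T = (bias_factor - 1) * temperature,
                 grid_s = seq(grid_min, grid_max, length.out = grid_n),
                 V = numeric(grid_n), dV = numeric(grid_n),
                 hills = data.frame(step = integer(), center = numeric(),
                                    height = numeric(), width = numeric())),
            class = "bias_state")
}

#' @export
print.bias_state <- function(x, ...) {
  cat(sprintf(
    "bias_state: %d hills (h0 %.2f, sigma %.2f A, gamma %.1f, T %.0f K)\n",
    nrow(x$hills), x$h0, x$sigma, x$bias_factor, x$temperature))
  invisible(x)
}

# linear interpolation on the bias grid, clamped at the edges
interp_grid <- function(gs, gv, s) {
  s <- pmin(pmax(s, gs[1]), gs[length(gs)])
  step <- gs[2] - gs[1]
  i <- pmin(pmax(floor((s - gs[1]) / step) + 1, 1), length(gs) - 1)
  f <- (s - gs[i]) / step
  gv[i] * (1 - f) + gv[i + 1] * f
}

#' Bias potential at a CV value
#' @param state a `bias_state`.
#' @param s CV value(s) (A).
#' @return bias energy (kJ/mol); vectorised in `s`.
#' @export
bias_energy <- function(state, s) interp_grid(state$grid_s, state$V, s)

#' Bias derivative dV/ds at a CV value
#' @inheritParams bias_energy
#' @return dV/ds (kJ/mol/A).
#' @export
bias_derivative <- function(state, s) interp_grid(state$grid_s, state$dV, s)

#' Deposit one well-tempered hill
#'
#' Appends a Gaussian of height `h = h0 exp(-V(s)/(kB DeltaT))`, with
#' `DeltaT = (gamma - 1) T`, centred at the current CV value; the grid
#' caches of `V` and `dV/ds` are updated.
#'
#' @param state a `bias_state`.
#' @param s CV value at deposition (A).
#' @param step integrator step (bookkeeping only).
#' @return the updated `bias_state`.
#' @export
deposit_hill <- function(state, s, step = NA_integer_) {
  h <- state$h0 * exp(-bias_energy(state, s) / (.kB * state$delta_T))
  u <- (state$grid_s - s) / state$sigma
  g <- h * exp(-u^2 / 2)
  state$V <- state$V + g
  state$dV <- state$dV - g * u / state$sigma
  state$hills <- rbind(state$hills,
                       data.frame(step = step, center = s, height = h,
                                  width = state$sigma))
  state
}

#' Half-harmonic wall restraint on the CV
#'
#' Zero inside `[lower, upper]`; `k (s - bound)^2` outside.
#'
#' @param lower,upper wall positions (A), defaults 5 and 20.
#' @param force_constant k (kJ/mol/A^2), default 10.
#' @return a `wall_restraint`.
#' @export
wall_restraint <- function(lower = 5, upper = 20, force_constant = 10) {
  if (lower >= upper) stop_ip("parameter_error", "wall needs lower < upper")
  structure(list(lower = lower, upper = upper, k = force_constant),
            class = "wall_restraint")
}

wall_energy_deriv <- function(wall, s) {
  if (s > wall$upper) {
    d <- s - wall$upper
    list(energy = wall$k * d^2, dE_ds = 2 * wall$k * d)
  } else if (s < wall$lower) {
    d <- wall$lower - s
    list(energy = wall$k * d^2, dE_ds = -2 * wall$k * d)
  } else list(energy = 0, dE_ds = 0)
}

#' Three-point angle restraint
#'
#' The angle at vertex `point_A` between the rays A->B and A->C, where C is
#' the mobile particle (the ion); the restraint penalises angles above
#' `max_angle` with `k (theta - max_angle)^2` (theta in radians).  With the
#' leaflet convention, A is the extracellular-leaflet phosphorus COM and B
#' the intracellular one; `vertex = "B"` selects the alternative reading of
#' the point ordering.
#'
#' @param point_A,point_B fixed points, length-3 (A).
#' @param max_angle maximum unpenalised angle (degrees), default 80.
#' @param force_constant k (kJ/mol/rad^2), default 100.
#' @param vertex `"A"` (default) or `"B"`: which fixed point is the vertex.
#' @return an `angle_restraint`.
#' @export
angle_restraint <- function(point_A, point_B, max_angle = 80,
                            force_constant = 100, vertex = c("A", "B")) {
  vertex <- match.arg(vertex)
  structure(list(A = as.numeric(point_A), B = as.numeric(point_B),
                 max_angle_rad = max_angle * pi / 180, k = force_constant,
                 vertex = vertex),
            class = "angle_restraint")
}

# energy and gradient (wrt the ion position C) of the angle restraint
angle_energy_grad <- function(ar, C) {
  if (ar$vertex == "A") { V <- ar$A; P <- ar$B } else { V <- ar$B; P <- ar$A }
  u <- P - V          # fixed ray
  v <- C - V          # ray to the ion
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-9 || nv < 1e-9)
    stop_ip("geometry_error", "angle undefined: coincident points")
  cth <- sum(u * v) / (nu * nv)
  cth <- min(max(cth, -1), 1)
  theta <- acos(cth)
  if (theta <= ar$max_angle_rad)
    return(list(energy = 0, grad = c(0, 0, 0), angle = theta))
  dtheta <- theta - ar$max_angle_rad
  sth <- sqrt(max(1 - cth^2, 1e-12))
  dcos_dC <- u / (nu * nv) - cth * v / nv^2
  dtheta_dC <- -dcos_dC / sth
  list(energy = ar$k * dtheta^2, grad = 2 * ar$k * dtheta * dtheta_dC,
       angle = theta)
}

#' Restraint energy and forces at a particle position
#'
#' Sums the CV wall and angle restraint contributions; forces are exact
#' analytic gradients (validated against finite differences in the tests).
#'
#' @param positions ion position, length-3 (A).
#' @param anchors anchor coordinates for the distance CV (n x 3).
#' @param wall a [wall_restraint()] or NULL.
#' @param angle an [angle_restraint()] or NULL.
#' @return list `energy` (kJ/mol) and `force` (length-3, kJ/mol/A).
#' @export
restraint_energy <- function(positions, anchors, wall = NULL, angle = NULL) {
  e <- 0; f <- c(0, 0, 0)
  if (!is.null(wall)) {
    cv <- cv_value(positions, anchors)
    we <- wall_energy_deriv(wall, cv$s)
    e <- e + we$energy
    f <- f - we$dE_ds * cv$grad
  }
  if (!is.null(angle)) {
    ae <- angle_energy_grad(angle, as.numeric(positions))
    e <- e + ae$energy
    f <- f - ae$grad
  }
  list(energy = e, force = f)
}

#' Radial double-well toy potential
#'
#' `U(s) = barrier ((s - m)^2 / w^2 - 1)^2` in the distance
#' `s = |r - com|`, with minima at `s_low` and `s_high`
#' (`m = (s_low + s_high)/2`, `w = (s_high - s_low)/2`) and barrier height
#' `barrier` at `s = m`.
#'
#' @param com centre, length-3 (A).
#' @param s_low,s_high minima positions (A).
#' @param barrier barrier height (kJ/mol).
#' @return `function(pos)` returning `list(energy, force)`.
#' @export
radial_double_well <- function(com, s_low, s_high, barrier) {
  m <- (s_low + s_high) / 2; w <- (s_high - s_low) / 2
  function(pos) {
    v <- as.numeric(pos) - com
    s <- sqrt(sum(v^2))
    q <- ((s - m)^2 / w^2) - 1
    dU_ds <- barrier * 2 * q * 2 * (s - m) / w^2
    grad_s <- if (s > 1e-12) v / s else c(0, 0, 0)
    list(energy = barrier * q^2, force = -dU_ds * grad_s)
  }
}

#' One-dimensional double-well potential on the x coordinate
#'
#' `U(x) = barrier ((x/x0)^2 - 1)^2`: minima at +-`x0`, barrier `barrier`
#' at x = 0.  The y and z coordinates are confined by a stiff harmonic so
#' the CV `s = x` is effectively one-dimensional.
#'
#' @param x0 minima positions (A).
#' @param barrier barrier height (kJ/mol).
#' @param k_confine confinement on y, z (kJ/mol/A^2).
#' @return `function(pos)` returning `list(energy, force)`.
#' @export
double_well_1d <- function(x0, barrier, k_confine = 100) {
  function(pos) {
    x <- pos[1]
    q <- (x / x0)^2 - 1
    fx <- -barrier * 2 * q * 2 * x / x0^2
    list(energy = barrier * q^2 + k_confine * (pos[2]^2 + pos[3]^2),
         force = c(fx, -2 * k_confine * pos[2], -2 * k_confine * pos[3]))
  }
}

#' Run overdamped Langevin dynamics with well-tempered metadynamics
#'
#' Integrates `dx = (F/friction) dt + sqrt(2 kB T dt / friction) xi` with
#' total force `F = F_potential + F_bias + F_restraints`, depositing a hill
#' on the distance CV every `bias$stride` steps.
#'
#' @param potential `function(pos) -> list(energy, force)`.
#' @param x0 initial position, length-3 (A).
#' @param anchors CV anchor coordinates (n x 3); the CV is
#'   `s = |pos - COM(anchors)|`.
#' @param n_steps number of integrator steps.
#' @param dt time step (ps, nominal).
#' @param friction friction coefficient (kJ/mol * ps / A^2).
#' @param temperature temperature (K).
#' @param bias a [bias_state()], or NULL for unbiased dynamics.
#' @param wall,angle optional restraints (see [restraint_energy()]).
#' @param seed RNG seed (mandatory for reproducibility).
#' @param record_stride store every k-th step, default 10.
#' @return list `samples` (data.frame `step, x, y, z, s, sx, sy, sz`),
#'   `bias` (final `bias_state` or NULL), `final` (last position).
#' @export
run_langevin_metad <- function(potential, x0, anchors, n_steps,
                               dt = 0.002, friction = 1,
                               temperature = 300, bias = NULL,
                               wall = NULL, angle = NULL, seed,
                               record_stride = 10L) {
  if (missing(seed)) stop_ip("parameter_error", "seed is mandatory")
  anchors <- as.matrix(anchors)
  com <- colMeans(anchors)
  noise_sd <- sqrt(2 * .kB * temperature * dt / friction)
  mob <- dt / friction
  n_rec <- floor(n_steps / record_stride)
  rec <- matrix(NA_real_, n_rec, 8)
  with_seed(seed, {
    x <- as.numeric(x0)
    ri <- 0L
    for (step in seq_len(n_steps)) {
      v <- x - com
      s <- sqrt(sum(v^2))
      grad_s <- if (s > 1e-12) v / s else c(0, 0, 0)
      p <- potential(x)
      frc <- p$force
      if (!is.null(bias)) {
        frc <- frc - bias_derivative(bias, s) * grad_s
        if (step %% bias$stride == 0L)
          bias <- deposit_hill(bias, s, step)
      }
      if (!is.null(wall)) {
        we <- wall_energy_deriv(wall, s)
        frc <- frc - we$dE_ds * grad_s
      }
      if (!is.null(angle)) {
        ae <- angle_energy_grad(angle, x)
        frc <- frc - ae$grad
      }
      x <- x + mob * frc + noise_sd * rnorm(3)
      if (any(!is.finite(x)) || max(abs(x)) > 1e5)
        stop_ip("integration_error",
                "trajectory diverged at step %d; reduce dt", step)
      if (step %% record_stride == 0L) {
        ri <- ri + 1L
        v <- x - com
        rec[ri, ] <- c(step, x, sqrt(sum(v^2)), v)
      }
    }
  })
  samples <- as.data.frame(rec[seq_len(ri), , drop = FALSE])
  names(samples) <- c("step", "x", "y", "z", "s", "sx", "sy", "sz")
  list(samples = samples, bias = bias, final = x)
}

#' Reconstruct the 1D free-energy profile from the bias
#'
#' Well-tempered estimator `F(s) = -((T + DeltaT)/DeltaT) V(s)`, shifted so
#' the minimum is zero.
#'
#' @param state a `bias_state` with at least one hill.
#' @param grid optional CV grid (default: the state's grid).
#' @return data.frame `(s, F)` (kJ/mol).
#' @export
reconstruct_fes <- function(state, grid = NULL) {
  if (!nrow(state$hills))
    stop_ip("analysis_error", "no hills deposited: FES undefined")
  s <- grid %||% state$grid_s
  V <- bias_energy(state, s)
  f <- -(state$temperature + state$delta_T) / state$delta_T * V
  data.frame(s = s, F = f - min(f))
}

#' Project the free energy onto two CV components
#'
#' Reweighted 2D histogram of sampled separation-vector components using
#' final-bias weights `w_t = exp(V(s_t) / kB T)`:
#' `F(a, b) = -kB T ln sum_t w_t 1[(a_t, b_t) in bin]`, shifted to min 0.
#' Unvisited cells are NA.
#'
#' @param samples samples data.frame from [run_langevin_metad()].
#' @param state the final `bias_state`.
#' @param components two of `"sx", "sy", "sz"`, default `c("sx", "sy")`.
#' @param bins number of bins per axis.
#' @return list `a_mid`, `b_mid`, `F` (matrix, kJ/mol), `components`.
#' @export
project_fes_2d <- function(samples, state, components = c("sx", "sy"),
                           bins = 60) {
  stopifnot(length(components) == 2,
            all(components %in% c("sx", "sy", "sz")))
  kT <- .kB * state$temperature
  w <- exp(bias_energy(state, samples$s) / kT)
  a <- samples[[components[1]]]; b <- samples[[components[2]]]
  abr <- range(a); bbr <- range(b)
  ia <- pmin(pmax(floor((a - abr[1]) / diff(abr) * bins) + 1, 1), bins)
  ib <- pmin(pmax(floor((b - bbr[1]) / diff(bbr) * bins) + 1, 1), bins)
  H <- matrix(0, bins, bins)
  for (i in seq_along(w)) H[ia[i], ib[i]] <- H[ia[i], ib[i]] + w[i]
  fe <- -kT * log(H)
  fe[!is.finite(fe)] <- NA
  fe <- fe - min(fe, na.rm = TRUE)
  list(a_mid = abr[1] + (seq_len(bins) - 0.5) * diff(abr) / bins,
       b_mid = bbr[1] + (seq_len(bins) - 0.5) * diff(bbr) / bins,
       F = fe, components = components)
}

#' Barrier height between the two deepest minima of a 1D profile
#'
#' Convenience diagnostic: finds the two lowest local minima of `F(s)` and
#' returns the highest point between them minus the deeper minimum.
#'
#' @param fes data.frame `(s, F)` from [reconstruct_fes()].
#' @return list `minima` (s positions), `barrier` (kJ/mol).
#' @export
fes_barrier <- function(fes) {
  f <- fes$F; s <- fes$s
  n <- length(f)
  locmin <- which(c(FALSE, f[2:(n - 1)] < f[1:(n - 2)] &
                      f[2:(n - 1)] <= f[3:n], FALSE))
  if (length(locmin) < 2)
    return(list(minima = s[locmin], barrier = NA_real_))
  locmin <- locmin[order(f[locmin])][1:2]
  locmin <- sort(locmin)
  barrier <- max(f[locmin[1]:locmin[2]]) - min(f[locmin])
  list(minima = s[locmin], barrier = barrier)
}
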