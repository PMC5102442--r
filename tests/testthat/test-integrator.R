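test_that("a free particle advances exactly at constant velocity", {
  st <- list(positions = matrix(0, 1, 2),
             velocities = matrix(c(3, -1), 1, 2), time = 0)
  r <- trapezoidal_step(st, function(y) y * 0, dt = 0.5)
  expect_true(r$converged)
  expect_lte(r$iterations, 2)
  expect_equal(r$state$positions, matrix(c(1.5, -0.5), 1, 2))
})

test_that("trapezoidal scheme is second-order accurate on the oscillator", {
  omega <- 2
  period <- 2 * pi / omega
  errs <- vapply(c(100, 200), function(nsteps) {
    dt <- period / nsteps
    st <- list(positions = matrix(c(1, 0), 1, 2),
               velocities = matrix(0, 1, 2), time = 0)
    set <- integrator_settings(max_fp_iterations = 50, fp_tolerance = 1e-12,
                               dt_initial = dt, dt_min = dt / 10, dt_max = dt)
    e <- 0
    for (k in seq_len(nsteps)) {
      r <- trapezoidal_step(st, function(y) -omega^2 * y, dt, set)
      expect_true(r$converged)
      st <- r$state
      e <- max(e, abs(st$positions[1, 1] -
                        oracle_oscillator(omega, st$time)))
    }
    e
  }, numeric(1))
  order <- log2(errs[1] / errs[2])
  expect_gt(order, 1.7)
  expect_lt(order, 2.3)
})

test_that("pinned particles do not move under any force", {
  cons <- list(pinned_ids = 1L, ref_positions = matrix(c(2, 3), 1, 2),
               boundary_ids = integer(0))
  st <- list(positions = matrix(c(2, 3), 1, 2),
             velocities = matrix(0, 1, 2), time = 0)
  r <- trapezoidal_step(st, function(y) matrix(c(1e6, -1e6), 1, 2), dt = 0.1,
                        constraints = cons)
  expect_true(r$converged)
  expect_equal(r$state$positions, matrix(c(2, 3), 1, 2))
  expect_equal(r$state$velocities, matrix(0, 1, 2))
})

test_that("time-step controller follows the shrink/grow/hold rules", {
  set <- integrator_settings(dt_grow = 1.2, dt_shrink = 0.5, grow_iters = 3,
                             dt_initial = 1e-4, dt_min = 1e-9, dt_max = 1e-3)
  # converged fast -> grow by 1.2, capped at dt_max
  expect_equal(adapt_dt(set, TRUE, 2, 1e-4), 1.2e-4)
  expect_equal(adapt_dt(set, TRUE, 1, 9.9e-4), 1e-3)
  # converged slowly -> hold
  expect_equal(adapt_dt(set, TRUE, 6, 1e-4), 1e-4)
  # rejected -> halve
  expect_equal(adapt_dt(set, FALSE, 8, 1e-4), 5e-5)
  # rejection below dt_min aborts with a diagnostic
  expect_error(adapt_dt(set, FALSE, 8, 1.5e-9), "underflow")
})

test_that("boundary conditions impose the radial velocity profile", {
  m <- build_circular_membrane(diameter = 40, spacing = 1, layer_width = 5)
  n <- nrow(m$positions_ref)
  st <- list(positions = m$positions_ref, velocities = matrix(0, n, 2))
  st <- apply_boundary_conditions(st, m, rate = 200)
  # particle on the +x rim moves at (rate, 0); on the +y rim at (0, rate)
  i <- which(m$positions_ref[, 1] == 19 & m$positions_ref[, 2] == 0)
  j <- which(m$positions_ref[, 1] == 0 & m$positions_ref[, 2] == 19)
  expect_equal(st$velocities[i, ], c(200, 0))
  expect_equal(st$velocities[j, ], c(0, 200))
  # interior untouched
  ctr <- which(m$positions_ref[, 1] == 0 & m$positions_ref[, 2] == 0)
  expect_equal(st$velocities[ctr, ], c(0, 0))
})

test_that("rim displacement integrates the constant boundary velocity exactly", {
  traj <- cached("rim_kinematics", {
    run_simulation(make_scaled_membrane(40, n_pins = 0, stop_ratio = 1.04))
  })
  last <- traj$snapshots[[length(traj$snapshots)]]
  m <- traj$membrane
  b <- m$boundary_layer_ids
  disp <- sqrt(rowSums((last$positions[b, ] - m$positions_ref[b, ])^2))
  expect_equal(disp, rep(200 * last$t, length(b)), tolerance = 1e-10)
})

test_that("compiled stepper matches the plain-R reference stepper", {
  m <- build_circular_membrane(diameter = 12, spacing = 1, layer_width = 3)
  m$boundary_layer_ids <- integer(0)   # free membrane: no constraints
  net <- build_bond_network(m, horizon = 3)
  mat <- material_model(K = 10, G = 5)
  rho <- mat$density_rho * mat$mass_scale * 1e-18
  set.seed(5)
  y0 <- m$positions_ref + matrix(rnorm(2 * nrow(m$positions_ref), 0, 0.02),
                                 ncol = 2)
  v0 <- matrix(0, nrow(m$positions_ref), 2)

  eng <- perimem:::pd_engine(m, net, mat)
  perimem:::cpp_engine_set_state(eng, y0, v0, 0)
  ok <- perimem:::cpp_engine_step(eng, 1e-5, 8L, 1e-10)
  yC <- perimem:::cpp_engine_state(eng)$positions

  ffn <- function(y) (internal_force_density(y, m, net, mat) +
                        short_range_force(y, m, net, mat)) / rho
  r <- trapezoidal_step(list(positions = y0, velocities = v0, time = 0),
                        ffn, 1e-5,
                        integrator_settings(fp_tolerance = 1e-10,
                                            dt_initial = 1e-5,
                                            dt_min = 1e-7, dt_max = 1e-4),
                        length_scale = m$spacing_h)
  expect_true(ok$converged && r$converged)
  expect_equal(yC, unname(r$state$positions), tolerance = 1e-9)
})

test_that("runs are deterministic and dt self-regulates below its cap", {
  t1 <- cached("det_a", {
    run_simulation(make_scaled_membrane(40, n_pins = 4, seed = 2,
                                        stop_ratio = 1.15))
  })
  t2 <- run_simulation(make_scaled_membrane(40, n_pins = 4, seed = 2,
                                            stop_ratio = 1.15))
  s1 <- t1$snapshots[[length(t1$snapshots)]]
  s2 <- t2$snapshots[[length(t2$snapshots)]]
  expect_identical(s1$positions, s2$positions)
  expect_identical(s1$damage, s2$damage)

  # the controller finds a stable step far below the configured maximum,
  # and rejections/regrowth leave a non-monotone dt trace
  lg <- t1$log
  expect_lt(median(lg[, "dt"]), t1$config$integrator$dt_max / 2)
  expect_gt(max(lg[, "dt"]), min(lg[, "dt"]))
})

test_that("damage is non-decreasing along a trajectory", {
  traj <- cached("det_a", {
    run_simulation(make_scaled_membrane(40, n_pins = 4, seed = 2,
                                        stop_ratio = 1.15))
  })
  dmg <- sapply(traj$snapshots, function(s) s$damage)
  expect_true(all(diff(t(dmg)) >= 0))
  # and snapshot times strictly increase
  ts <- sapply(traj$snapshots, function(s) s$t)
  expect_true(all(diff(ts) > 0))
})
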