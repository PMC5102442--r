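#' Integrator settings
#'
#' Settings for the implicit trapezoidal time stepper.  The nonlinear update
#' is solved by fixed-point iteration (not Newton's method); the defaults of
#' at most 8 iterations to a relative tolerance of 1e-6 are the study
#' conditions.  A step whose iteration fails to converge is rejected and
#' retried with a smaller time step, so the step size self-regulates: it
#' shrinks by orders of magnitude while bonds are breaking and recovers in
#' quiescent phases.  The controller constants (`dt_grow = 1.2`,
#' `dt_shrink = 0.5`, growth after convergence in at most `grow_iters = 3`
#' iterations) are configurable.
#'
#' @param max_fp_iterations Maximum fixed-point iterations per step.
#' @param fp_tolerance Relative position-update tolerance for convergence.
#' @param dt_initial,dt_min,dt_max Time-step bounds (s).
#' @param dt_grow,dt_shrink Multiplicative controller factors
#'   (`dt_shrink < 1 < dt_grow`).
#' @param grow_iters Grow the step when convergence took at most this many
#'   iterations.
#' @return An object of class `pd_integrator_settings`.
#' @export
integrator_settings <- function(max_fp_iterations = 8L, fp_tolerance = 1e-6,
                                dt_initial = 1e-4, dt_min = 1e-12,
                                dt_max = 2e-3, dt_grow = 1.2,
                                dt_shrink = 0.5, grow_iters = 3L) {
  stopifnot(dt_min > 0, dt_min <= dt_initial, dt_initial <= dt_max,
            dt_shrink < 1, dt_grow > 1, max_fp_iterations >= 1,
            fp_tolerance > 0)
  structure(list(max_fp_iterations = as.integer(max_fp_iterations),
                 fp_tolerance = fp_tolerance, dt_initial = dt_initial,
                 dt_min = dt_min, dt_max = dt_max, dt_grow = dt_grow,
                 dt_shrink = dt_shrink, grow_iters = as.integer(grow_iters)),
            class = "pd_integrator_settings")
}

#' One implicit trapezoidal step (reference implementation)
#'
#' Advances `y_{n+1} = y_n + dt/2 (v_n + v_{n+1})`,
#' `v_{n+1} = v_n + dt/2 (a_n + a_{n+1})` by fixed-point iteration starting
#' from a forward-Euler predictor, with kinematic constraints (pins and
#' boundary-layer velocities) re-imposed after every iterate.  Convergence
#' is reached when the largest position change between successive iterates
#' falls below `fp_tolerance` relative to the reference length scale (the
#' lattice spacing in membrane runs); an iterate change that grows instead
#' of shrinking flags divergence immediately.  On non-convergence the state
#' is returned unchanged and flagged so the caller can shrink the step
#' ([adapt_dt()]).
#'
#' This plain-R path takes an arbitrary acceleration function and is the
#' test oracle for the compiled stepper used by [run_simulation()].
#'
#' @param state List with `positions`, `velocities` (N x 2 matrices),
#'   optional `accelerations`, and `time`.
#' @param forces_fn Function `f(positions)` returning N x 2 accelerations
#'   (force density already divided by the scaled density).
#' @param dt Time step (s).
#' @param settings An [integrator_settings()] object.
#' @param constraints Optional list with `pinned_ids`, `ref_positions`,
#'   `boundary_ids`, `boundary_velocity` (n_b x 2).
#' @param length_scale Reference length (um) against which the convergence
#'   tolerance is measured; the lattice spacing in membrane runs.
#' @return List `(state, converged, iterations)`; `state` is the new state
#'   when converged, the input state otherwise.
#' @export
trapezoidal_step <- function(state, forces_fn, dt,
                             settings = integrator_settings(),
                             constraints = NULL, length_scale = 1) {
  y0 <- as.matrix(state$positions)
  v0 <- as.matrix(state$velocities)
  a0 <- state$accelerations
  if (is.null(a0)) a0 <- forces_fn(y0)
  project <- function(y, v) {
    if (!is.null(constraints)) {
      p <- constraints$pinned_ids
      if (length(p)) {
        y[p, ] <- constraints$ref_positions[p, , drop = FALSE]
        v[p, ] <- 0
      }
      b <- constraints$boundary_ids
      if (length(b)) {
        v[b, ] <- constraints$boundary_velocity
        y[b, ] <- y0[b, , drop = FALSE] + dt * constraints$boundary_velocity
      }
    }
    list(y = y, v = v)
  }
  pr <- project(y0 + dt * v0, v0 + dt * a0)
  y1 <- pr$y; v1 <- pr$v
  converged <- FALSE
  iters <- 0L
  prev_delta <- Inf
  for (k in seq_len(settings$max_fp_iterations)) {
    iters <- k
    a1 <- forces_fn(y1)
    vn <- v0 + dt / 2 * (a0 + a1)
    yn <- y0 + dt / 2 * (v0 + vn)
    pr <- project(yn, vn)
    delta <- max(abs(pr$y - y1))
    y1 <- pr$y; v1 <- pr$v
    if (!is.finite(delta)) break
    # position change in units of the reference length scale: an absolute
    # measure that tightens where the dynamics localise (crack tips)
    if (delta <= settings$fp_tolerance * length_scale) {
      converged <- TRUE
      break
    }
    # a growing iterate change means the fixed-point map is divergent at
    # this dt; give up immediately so the controller can shrink the step
    if (k > 1 && delta > prev_delta) break
    prev_delta <- delta
  }
  if (!converged)
    return(list(state = state, converged = FALSE, iterations = iters))
  list(state = list(positions = y1, velocities = v1,
                    accelerations = forces_fn(y1),
                    time = (state$time %||% 0) + dt),
       converged = TRUE, iterations = iters)
}

#' Adaptive time-step rule
#'
#' Rejected step: shrink (`dt * dt_shrink`, floored at `dt_min`) and retry.
#' Converged in at most `grow_iters` iterations: grow (`dt * dt_grow`,
#' capped at `dt_max`).  Otherwise leave the step unchanged.
#'
#' @param settings An [integrator_settings()] object.
#' @param converged Did the last attempted step converge?
#' @param iterations Fixed-point iterations used by the last attempt.
#' @param dt Current time step (s).
#' @return The new time step (s).  Signals an error if a rejected step would
#'   push the step below `dt_min`.
#' @export
adapt_dt <- function(settings, converged, iterations, dt) {
  stopifnot(inherits(settings, "pd_integrator_settings"))
  if (!converged) {
    new_dt <- dt * settings$dt_shrink
    if (new_dt < settings$dt_min)
      stop(sprintf(
        "time step underflow: dt = %.3e would fall below dt_min = %.3e",
        new_dt, settings$dt_min), call. = FALSE)
    return(max(new_dt, settings$dt_min))
  }
  if (iterations <= settings$grow_iters)
    return(min(dt * settings$dt_grow, settings$dt_max))
  dt
}

#' Impose kinematic boundary conditions
#'
#' Sets each boundary-layer particle's velocity to `rate` times the outward
#' unit radial vector of its reference position (the rim expands at a
#' constant radial speed, emulating the tank-tread advance of the membrane
#' edge), zeroes pinned particles' velocities and resets their positions to
#' the reference configuration.
#'
#' @param state List with `positions` and `velocities` (N x 2).
#' @param membrane A [build_circular_membrane()] object.
#' @param rate Radial expansion speed (um/s).
#' @return The constrained state.
#' @export
apply_boundary_conditions <- function(state, membrane, rate = 200) {
  stopifnot(inherits(membrane, "pd_membrane"))
  y <- as.matrix(state$positions)
  v <- as.matrix(state$velocities)
  b <- membrane$boundary_layer_ids
  if (length(b)) {
    ref <- membrane$positions_ref[b, , drop = FALSE]
    r <- sqrt(ref[, 1]^2 + ref[, 2]^2)
    r[r == 0] <- 1
    v[b, ] <- rate * ref / r
  }
  p <- membrane$pinned_ids
  if (length(p)) {
    y[p, ] <- membrane$positions_ref[p, , drop = FALSE]
    v[p, ] <- 0
  }
  state$positions <- y
  state$velocities <- v
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a
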