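#' Full simulation configuration
#'
#' Bundles geometry, material, pinning, loading and integrator settings for
#' one rupture simulation.  All defaults are the study conditions for the
#' full-scale membrane: 200 um diameter, 1 um spacing, 3 um horizon, 5 nm
#' thickness, 10 um driven boundary layer, K = 10 MPa, rho = 1000 kg/m^3
#' mass-scaled by 1e8, 15 % critical stretch, contact constant 2.7e-8 and a
#' 200 um/s radial expansion rate.  The run stops when the expansion ratio
#' D/D0 reaches `stop_ratio` (the natural progress coordinate of the
#' expansion) or at
#' `t_max`.
#'
#' @param diameter,spacing,horizon,thickness,layer_width Geometry (um).
#' @param material A [material_model()] object.
#' @param n_pins Number of pinning sites (ignored when `pin_coordinates`
#'   given).
#' @param pin_seed Seed for random pin placement.
#' @param pin_region Optional disc `list(center, radius)` for clustered pins.
#' @param pin_coordinates Optional explicit n x 2 pin coordinates (um).
#' @param loading_rate Radial boundary speed (um/s).
#' @param integrator An [integrator_settings()] object.
#' @param stop_ratio Target expansion ratio D/D0.
#' @param t_max Maximum simulated time (s).
#' @param snapshot_dt Snapshot cadence in simulated time (s); cadence in
#'   time, not steps, so the adaptive step does not alias the output.
#' @param max_steps Safety cap on accepted steps.
#' @return An object of class `pd_run_config`.
#' @export
run_config <- function(diameter = 200, spacing = 1, horizon = 3,
                       thickness = 0.005, layer_width = 10,
                       material = material_model(),
                       n_pins = 0, pin_seed = 1L, pin_region = NULL,
                       pin_coordinates = NULL,
                       loading_rate = 200,
                       integrator = integrator_settings(),
                       stop_ratio = 1.5, t_max = 10,
                       snapshot_dt = 0.005, max_steps = 2e6) {
  stopifnot(inherits(material, "pd_material"),
            inherits(integrator, "pd_integrator_settings"),
            stop_ratio >= 1, loading_rate >= 0)
  structure(list(diameter = diameter, spacing = spacing, horizon = horizon,
                 thickness = thickness, layer_width = layer_width,
                 material = material, n_pins = n_pins,
                 pin_seed = as.integer(pin_seed), pin_region = pin_region,
                 pin_coordinates = pin_coordinates,
                 loading_rate = loading_rate, integrator = integrator,
                 stop_ratio = stop_ratio, t_max = t_max,
                 snapshot_dt = snapshot_dt, max_steps = max_steps),
            class = "pd_run_config")
}

#' @export
print.pd_run_config <- function(x, ...) {
  cat("Peridynamic rupture run configuration\n")
  cat(sprintf("  membrane: D0 = %g um, h = %g um, delta = %g um, layer %g um\n",
              x$diameter, x$spacing, x$horizon, x$layer_width))
  cat(sprintf("  material: K = %g MPa, G = %g MPa, s_c = %g, mass x %g\n",
              x$material$bulk_K, x$material$shear_G,
              x$material$critical_stretch_sc, x$material$mass_scale))
  cat(sprintf("  pins: %s, loading %g um/s, stop at D/D0 = %g\n",
              if (!is.null(x$pin_coordinates)) "explicit" else x$n_pins,
              x$loading_rate, x$stop_ratio))
  invisible(x)
}

#' Run a rupture simulation
#'
#' Builds the lattice, bond network and pinning set from `config`, then
#' advances the equation of motion with the compiled implicit trapezoidal
#' stepper under adaptive time-step control.  Each accepted step applies the
#' kinematic boundary conditions, checks bonds against the critical stretch
#' (once per accepted step, after the position update), and records a
#' snapshot whenever the simulated time passes the cadence.  All randomness
#' (pin placement) flows from `config$pin_seed`, so identical configurations
#' reproduce identical trajectories.
#'
#' @param config A [run_config()] object.
#' @param verbose Print a one-line summary at the end?
#' @return An object of class `pd_trajectory`: list with `snapshots` (each
#'   holding `t`, `positions`, `velocities`, `damage`, `ratio`,
#'   `broken_bonds`), `log` (per accepted step: t, dt, iterations,
#'   new_broken, ratio), `first_cross` (per particle, first time damage
#'   reached 0.5; NA if never), `status`, and the membrane/network/config.
#' @export
run_simulation <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pd_run_config"))
  membrane <- build_circular_membrane(config$diameter, config$spacing,
                                      config$thickness, config$layer_width)
  if (!is.null(config$pin_coordinates)) {
    pins <- assign_pinning(membrane, n = nrow(config$pin_coordinates),
                           coordinates = config$pin_coordinates)
  } else {
    pins <- assign_pinning(membrane, n = config$n_pins,
                           seed = config$pin_seed, region = config$pin_region)
  }
  membrane <- set_pinning(membrane, pins)
  network <- build_bond_network(membrane, config$horizon)
  eng <- pd_engine(membrane, network, config$material,
                   loading_rate = config$loading_rate)
  s <- config$integrator
  res <- cpp_engine_run(eng, list(
    dt_initial = s$dt_initial, dt_min = s$dt_min, dt_max = s$dt_max,
    dt_grow = s$dt_grow, dt_shrink = s$dt_shrink,
    grow_iters = s$grow_iters, max_fp_iterations = s$max_fp_iterations,
    fp_tolerance = s$fp_tolerance, stop_ratio = config$stop_ratio,
    t_max = config$t_max, max_steps = config$max_steps,
    snapshot_dt = config$snapshot_dt))
  snaps <- res$snapshots
  # the loop always appends the final state; drop it if it duplicates the
  # last cadence snapshot
  if (length(snaps) >= 2 &&
      isTRUE(all.equal(snaps[[length(snaps)]]$t,
                       snaps[[length(snaps) - 1]]$t)))
    snaps[[length(snaps)]] <- NULL
  fc <- res$first_cross
  fc[fc < 0] <- NA_real_
  traj <- structure(list(snapshots = snaps, log = res$log,
                         first_cross = fc, status = res$status,
                         steps = res$steps, membrane = membrane,
                         network = network, pinning = pins,
                         config = config), class = "pd_trajectory")
  if (verbose) print(traj)
  traj
}

#' Expansion ratio of a snapshot
#'
#' `D/D0 = 2 max_i |y_i| / D0`: the diameter of the expanded membrane over
#' the initial diameter, the progress coordinate of the expansion.
#'
#' @param snapshot One element of `trajectory$snapshots` (or a positions
#'   matrix).
#' @param diameter_0 Initial diameter (um); taken from the snapshot when
#'   absent there.
#' @return Dimensionless D/D0.
#' @export
expansion_ratio <- function(snapshot, diameter_0 = NULL) {
  y <- if (is.list(snapshot)) snapshot$positions else as.matrix(snapshot)
  if (is.null(diameter_0)) {
    if (is.list(snapshot) && !is.null(snapshot$ratio))
      return(snapshot$ratio)
    stop("'diameter_0' needed when the snapshot carries no metadata",
         call. = FALSE)
  }
  2 * sqrt(max(y[, 1]^2 + y[, 2]^2)) / diameter_0
}

#' @export
print.pd_trajectory <- function(x, ...) {
  last <- x$snapshots[[length(x$snapshots)]]
  cat("Peridynamic rupture trajectory\n")
  cat(sprintf("  particles: %d, snapshots: %d, accepted steps: %d\n",
              nrow(last$positions), length(x$snapshots), as.integer(x$steps)))
  cat(sprintf("  final t = %.4g s, D/D0 = %.3f, broken bond pairs = %d\n",
              last$t, last$ratio, as.integer(last$broken_bonds)))
  cat(sprintf("  stop condition: %s\n", x$status))
  invisible(x)
}

#' @export
summary.pd_trajectory <- function(object, ...) {
  lg <- object$log
  cat("Trajectory summary\n")
  print(object)
  if (nrow(lg)) {
    cat(sprintf("  dt range: %.3g .. %.3g s (median %.3g)\n",
                min(lg[, "dt"]), max(lg[, "dt"]), median(lg[, "dt"])))
    cat(sprintf("  fixed-point iterations: median %g, max %g\n",
                median(lg[, "iterations"]), max(lg[, "iterations"])))
  }
  n_nuc <- sum(!is.na(object$first_cross))
  cat(sprintf("  particles with damage >= 0.5: %d\n", n_nuc))
  invisible(object)
}

#' @export
plot.pd_trajectory <- function(x, snapshot = length(x$snapshots), ...) {
  s <- x$snapshots[[snapshot]]
  dmg <- pmin(pmax(s$damage, 0), 1)
  pal <- grDevices::colorRampPalette(c("grey70", "orange", "red"))(101)
  plot(s$positions, asp = 1, pch = 16, cex = 0.4,
       col = pal[1 + round(100 * dmg)],
       xlab = "x (um)", ylab = "y (um)",
       main = sprintf("t = %.3g s, D/D0 = %.3f", s$t, s$ratio), ...)
  if (length(x$membrane$pinned_ids))
    graphics::points(x$membrane$positions_ref[x$membrane$pinned_ids, ,
                                              drop = FALSE],
                     col = "blue", cex = 1.2, lwd = 2)
  invisible(x)
}

#' Particles at the onset of rupture
#'
#' The onset is the earliest time any particle's damage reached 0.5; the
#' returned set holds every particle whose damage crossed 0.5 within
#' `window` seconds of that onset.  Used to check that ruptures nucleate at
#' the pinning sites.
#'
#' By default the statistic is restricted to the membrane interior: the
#' driven boundary layer carries no radial strain, so its tension is about
#' half the interior's and the bonds bridging the layer junction tear as a
#' circular ring early in every run.  This is the rim rupture that the
#' original imaging analysis removed manually from the binary images;
#' `exclude_rim` applies the matching rule here (drop particles within two
#' horizons of the layer junction or beyond, the zone the ring tear reaches).
#'
#' @param trajectory A [run_simulation()] result.
#' @param window Time window after the first crossing (s).
#' @param exclude_rim Restrict to interior particles (reference radius less
#'   than `D0/2 - layer_width - 2 * horizon`)?
#' @return List with `onset_time` (NA if no rupture), `ids` (particle
#'   indices), and `distances_to_pin` (um; distance from each onset particle
#'   to the nearest pinning site, NA when there are no pins).
#' @export
rupture_onset <- function(trajectory, window = 0, exclude_rim = TRUE) {
  fc <- trajectory$first_cross
  if (exclude_rim) {
    m <- trajectory$membrane
    rr <- sqrt(rowSums(m$positions_ref^2))
    r_cut <- m$diameter_0 / 2 - m$layer_width -
      2 * trajectory$network$horizon_delta
    fc[rr >= r_cut] <- NA_real_
  }
  if (all(is.na(fc)))
    return(list(onset_time = NA_real_, ids = integer(0),
                distances_to_pin = numeric(0)))
  onset <- min(fc, na.rm = TRUE)
  ids <- which(!is.na(fc) & fc <= onset + window)
  pins <- trajectory$membrane$pinned_ids
  pos <- trajectory$membrane$positions_ref
  d <- if (length(pins) == 0) rep(NA_real_, length(ids)) else
    vapply(ids, function(i) {
      sqrt(min((pos[pins, 1] - pos[i, 1])^2 + (pos[pins, 2] - pos[i, 2])^2))
    }, numeric(1))
  list(onset_time = onset, ids = ids, distances_to_pin = d)
}

#' Count distinct rupture nucleation sites
#'
#' Clusters the particles whose damage crossed 0.5 within `window` seconds
#' of the interior rupture onset (see [rupture_onset()]) into spatially
#' connected groups (reference distance at most `link` apart) and returns
#' the number of groups.  This is the count of independently nucleating
#' pores, which is robust against the rapid coalescence that makes pore
#' counts at any single later expansion ratio ambiguous.
#'
#' @param trajectory A [run_simulation()] result.
#' @param window Crossing-time window after onset (s).
#' @param link Cluster linkage distance (um); default `2 h`.
#' @param exclude_rim Passed to [rupture_onset()].
#' @return Integer count of nucleation clusters (0 when no rupture).
#' @export
count_nucleation_sites <- function(trajectory, window = 2e-3,
                                   link = 2 * trajectory$config$spacing,
                                   exclude_rim = TRUE) {
  on <- rupture_onset(trajectory, window = window, exclude_rim = exclude_rim)
  ids <- on$ids
  if (length(ids) == 0L) return(0L)
  pos <- trajectory$membrane$positions_ref[ids, , drop = FALSE]
  # single-linkage clustering by union-find over close pairs
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (a in seq_along(ids)) for (b in seq_len(a - 1L)) {
    if (sum((pos[a, ] - pos[b, ])^2) <= link^2) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[ra] <- rb
    }
  }
  length(unique(vapply(seq_along(ids), find, integer(1))))
}
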