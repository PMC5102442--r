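# Shared simulation runs, memoised so the expensive fixtures are computed
# once per test session and reused across test files.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache, inherits = FALSE))
    assign(key, force(expr), envir = .sim_cache)
  get(key, envir = .sim_cache, inherits = FALSE)
}

# 60 um fixture, G = 0, n = 4 scattered pins: nucleation test vehicle
nucleation_runs <- function(seeds = 1:5) {
  lapply(seeds, function(s) cached(paste0("nuc", s), {
    run_simulation(make_scaled_membrane(60, n_pins = 4, seed = s,
                                        stop_ratio = 1.1))
  }))
}

# 60 um fixture, n = 6 pins fixed per seed, shear sweep: morphology vehicle
morphology_D <- function(seeds = 1:5, G_values = c(0, 2.5, 7.5)) {
  vapply(G_values, function(G) {
    vapply(seeds, function(s) {
      cached(sprintf("morphD_s%d_G%g", s, G), {
        traj <- run_simulation(make_scaled_membrane(
          60, n_pins = 6, seed = s,
          material = material_model(K = 10, G = G)))
        snap <- traj$snapshots[[length(traj$snapshots)]]
        suppressWarnings(
          box_count_dimension(rasterize_rupture(snap))$D)
      })
    }, numeric(1))
  }, numeric(length(seeds)))
}

# 40 um fixture, G = 5: mass-scaling sweep
mass_scaling_D <- function(seeds = 1:3, scales = c(1e4, 1e6, 1e8)) {
  vapply(scales, function(ms) {
    vapply(seeds, function(s) {
      cached(sprintf("massD_s%d_m%g", s, ms), {
        traj <- run_simulation(make_scaled_membrane(
          40, n_pins = 4, seed = s,
          material = material_model(K = 10, G = 5, mass_scale = ms)))
        snap <- traj$snapshots[[length(traj$snapshots)]]
        suppressWarnings(
          box_count_dimension(rasterize_rupture(snap))$D)
      })
    }, numeric(1))
  }, numeric(length(seeds)))
}

# small membrane + network + material used by several force tests
small_system <- function() {
  cached("small_system", {
    m <- build_circular_membrane(diameter = 20, spacing = 1)
    list(membrane = m,
         network = build_bond_network(m, horizon = 3),
         material = material_model(K = 10, G = 5))
  })
}
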