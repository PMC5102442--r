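#' Uniformly strained square patch
#'
#' Builds an `n_side` x `n_side` square lattice patch and deforms it by a
#' uniform small-strain tensor, `y = (I + strain) x`.  Used to calibrate and
#' verify the LPS force coefficients against closed-form 2D elasticity: the
#' interior stress of the strained patch must reproduce
#' `sigma = K tr(eps) I + 2 G dev(eps)` away from the free-edge skin.
#'
#' @param n_side Particles per side; must be at least `12 delta / h` so a
#'   genuinely interior region exists.
#' @param h Lattice spacing (um).
#' @param strain 2 x 2 small-strain tensor.
#' @param delta Horizon (um), used only for the size check.
#' @return List with `membrane`, `network`, `positions` (deformed), and
#'   `strain`.
#' @export
make_patch <- function(n_side = 40, h = 1,
                       strain = matrix(0, 2, 2), delta = 3 * h) {
  if (n_side < 12 * delta / h)
    stop(sprintf("patch too small: n_side must be >= %g", 12 * delta / h),
         call. = FALSE)
  strain <- matrix(as.numeric(strain), 2, 2)
  idx <- seq_len(n_side) - (n_side + 1) / 2
  grid <- expand.grid(i = idx, j = idx)
  pos <- cbind(x = grid$i * h, y = grid$j * h)
  membrane <- structure(list(
    positions_ref = pos, spacing_h = h, thickness_eps = 0.005,
    area_per_particle = h^2, diameter_0 = n_side * h,
    layer_width = h, boundary_layer_ids = integer(0),
    pinned_ids = integer(0)), class = "pd_membrane")
  network <- build_bond_network(membrane, delta)
  F <- diag(2) + strain
  list(membrane = membrane, network = network,
       positions = pos %*% t(F), strain = strain)
}

#' Interior particles of a patch
#'
#' Indices of particles farther than `skin` from every edge of the patch.
#'
#' @param patch A [make_patch()] result.
#' @param skin Width of the boundary skin to exclude (um); default 3 delta.
#' @return Integer particle indices.
#' @export
patch_interior <- function(patch, skin = 3 * patch$network$horizon_delta) {
  pos <- patch$membrane$positions_ref
  lim <- max(abs(pos)) - skin
  which(abs(pos[, 1]) <= lim & abs(pos[, 2]) <= lim)
}

#' Stress transmitted through a cut of a strained patch
#'
#' Measures the force flux through a virtual line cut of the patch: the sum
#' of pairwise bond force densities crossing the cut, restricted to the
#' interior band (away from a `3 delta` skin), divided by the band length
#' and the membrane thickness.  Under uniform strain this is the membrane's
#' effective 2D stress (in MPa) and is the patch-test measurement compared
#' against closed-form elasticity.
#'
#' @param patch A [make_patch()] result.
#' @param material A [material_model()] object.
#' @param direction `"x"` for a vertical cut measuring (sigma_xx,
#'   sigma_yx), `"y"` for a horizontal cut measuring (sigma_xy, sigma_yy).
#' @return Numeric length-2 vector: the traction components on the cut.
#' @export
stress_through_cut <- function(patch, material, direction = c("x", "y")) {
  direction <- match.arg(direction)
  membrane <- patch$membrane
  network <- patch$network
  pos <- patch$positions
  ref <- membrane$positions_ref
  eps <- membrane$thickness_eps
  A <- membrane$area_per_particle
  fs <- bond_force_states(pos, membrane, network, material)
  # t_ij + t_ji per directed pair: add the reverse bond's scalar state
  tsum <- fs$t + fs$t[network$brev + 1L]
  ax <- if (direction == "x") 1L else 2L   # axis normal to the cut
  skin <- 3 * network$horizon_delta
  lim <- max(abs(ref)) - skin
  cut_pos <- 0.25 * membrane$spacing_h    # between lattice columns
  cross <- ref[fs$i, ax] < cut_pos & ref[fs$j, ax] > cut_pos
  # half-open source-side band: every bond offset then crosses the band cut
  # exactly |xi_axis| / h^2 times per unit length, so the flux normalisation
  # is exact and free of endpoint double counting
  src_t <- ref[fs$i, 3L - ax]
  band <- src_t >= -lim & src_t < lim
  sel <- cross & band
  L <- 2 * lim
  # pair force = eps^2 (t_ij + t_ji) M A_i A_j; stress = flux / (L eps)
  fx <- sum(tsum[sel] * fs$ux[sel]) * A * A * eps^2
  fy <- sum(tsum[sel] * fs$uy[sel]) * A * A * eps^2
  c(fx, fy) / (L * eps)
}

#' Closed-form 2D stress for a uniform strain
#'
#' `sigma = K tr(eps) I + 2 G dev(eps)` with the areal moduli of the
#' membrane model; the target of the patch test.
#'
#' @param material A [material_model()] object.
#' @param strain 2 x 2 small-strain tensor.
#' @return 2 x 2 stress tensor (MPa).
#' @export
elastic_stress_2d <- function(material, strain) {
  strain <- matrix(as.numeric(strain), 2, 2)
  strain <- (strain + t(strain)) / 2
  tr <- sum(diag(strain))
  material$bulk_K * tr * diag(2) +
    2 * material$shear_G * (strain - tr / 2 * diag(2))
}

#' Deterministic analytic-fractal rasters
#'
#' Binary rasters with known fractal dimension, used to validate the
#' box-counting estimator: a horizontal line (D = 1), a filled square
#' (D = 2), and a Sierpinski triangle of the requested recursion level
#' (similarity dimension log 3 / log 2 ~ 1.585).
#'
#' @param kind One of `"line"`, `"square"`, `"sierpinski"`.
#' @param level Recursion level (sierpinski only; the raster holds
#'   `3^level` filled blocks).
#' @param size Image side in pixels; must be a power of two.
#' @return A `pd_rupture_mask`-classed object whose `mask` is the raster.
#' @export
make_fractal_raster <- function(kind = c("line", "square", "sierpinski"),
                                level = 7, size = 512) {
  kind <- match.arg(kind)
  if (bitwAnd(size, size - 1L) != 0L || size < 8)
    stop("'size' must be a power of two (>= 8)", call. = FALSE)
  m <- matrix(FALSE, size, size)
  if (kind == "line") {
    m[size %/% 2, ] <- TRUE
  } else if (kind == "square") {
    m[, ] <- TRUE
  } else {
    stopifnot(level >= 1)
    if (2^level > size)
      stop("'level' too deep for this raster size", call. = FALSE)
    block <- size %/% 2^level
    cells <- expand.grid(i = 0:(2^level - 1), j = 0:(2^level - 1))
    keep <- cells[bitwAnd(cells$i, cells$j) == 0L, ]
    for (k in seq_len(nrow(keep))) {
      r <- keep$i[k] * block
      c <- keep$j[k] * block
      m[(r + 1):(r + block), (c + 1):(c + block)] <- TRUE
    }
  }
  structure(list(mask = m, void = m, in_hull = matrix(TRUE, size, size),
                 origin = c(0, 0), resolution = 1, rim_removed = FALSE,
                 empty = !any(m)),
            class = "pd_rupture_mask")
}

#' Scaled membrane run configuration
#'
#' A [run_config()] equal to the full-scale study conditions except for the
#' diameter, giving a test vehicle that ruptures in minutes of CPU time.
#' Pins are scattered uniformly over the interior, or confined to a small
#' central disc when `cluster = TRUE` (the clustered-pin layout whose pores
#' merge into a single floral pore).
#'
#' @param diameter Membrane diameter (um); at least 20 lattice spacings.
#' @param n_pins Number of pinning sites.
#' @param cluster Confine pins to a central disc?
#' @param seed Pin placement seed.
#' @param cluster_radius Radius of the clustering disc (um).
#' @param ... Passed on to [run_config()] (e.g. `material`, `stop_ratio`).
#' @return A `pd_run_config`.
#' @export
make_scaled_membrane <- function(diameter = 60, n_pins = 4, cluster = FALSE,
                                 seed = 1L, cluster_radius = diameter / 8,
                                 ...) {
  spacing <- 1
  if (diameter < 20 * spacing)
    stop("'diameter' must be at least 20 lattice spacings", call. = FALSE)
  region <- if (cluster) list(center = c(0, 0), radius = cluster_radius)
            else NULL
  run_config(diameter = diameter, n_pins = n_pins, pin_seed = seed,
             pin_region = region, ...)
}
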