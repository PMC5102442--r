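#' Material model for the membrane
#'
#' Collects the elastic, inertial and failure parameters of the state-based
#' linear peridynamic solid (LPS) membrane model.  The 2D reduction treats
#' `K` and `G` as the areal bulk and shear moduli of the film, so that a
#' fluid membrane (`G = 0`) still resists areal dilatation; the resulting
#' in-plane stress under uniform small strain is
#' `sigma = K tr(eps) I + 2 G dev(eps)`.
#'
#' The density is mass-scaled: the simulated density is
#' `rho * mass_scale`, which enlarges the stable time step by
#' `sqrt(mass_scale)` and makes second-long spreading processes tractable.
#' Defaults are the study conditions: `K = 10` MPa, `rho = 1000` kg/m^3,
#' `mass_scale = 1e8`, critical stretch 15 %, contact constant
#' `c = 2.7e-8`.
#'
#' @param K Bulk modulus (MPa).
#' @param G Shear modulus (MPa); 0 models a fluid membrane.
#' @param rho Physical mass density (kg/m^3).
#' @param mass_scale Dimensionless density scaling factor.
#' @param critical_stretch Relative bond elongation beyond which a bond
#'   breaks irreversibly (tension only).
#' @param contact_scale_c Dimensionless scale `c` of the short-range
#'   repulsion prefactor `C_sr = c * K * pi / delta^5`.
#' @param contact_cutoff_mult Search radius for short-range forces, in
#'   multiples of the lattice spacing.
#' @param Csr Optional explicit short-range prefactor (MPa / um^5),
#'   overriding the `c`-based expression.
#' @return An object of class `pd_material`.
#' @examples
#' material_model(K = 10, G = 5)
#' @export
material_model <- function(K = 10, G = 0, rho = 1000, mass_scale = 1e8,
                           critical_stretch = 0.15, contact_scale_c = 2.7e-8,
                           contact_cutoff_mult = 6, Csr = NULL) {
  if (!is.numeric(K) || K <= 0) stop("'K' must be > 0", call. = FALSE)
  if (!is.numeric(G) || G < 0) stop("'G' must be >= 0", call. = FALSE)
  if (!is.numeric(critical_stretch) || critical_stretch <= 0)
    stop("'critical_stretch' must be > 0", call. = FALSE)
  nu <- poisson_ratio(K, G)
  if (nu <= -1 || nu > 0.5)
    stop("moduli give a Poisson ratio outside (-1, 0.5]", call. = FALSE)
  structure(list(
    bulk_K = K, shear_G = G, density_rho = rho, mass_scale = mass_scale,
    critical_stretch_sc = critical_stretch,
    contact_scale_c = contact_scale_c,
    contact_cutoff_mult = contact_cutoff_mult,
    Csr_override = Csr
  ), class = "pd_material")
}

#' @export
print.pd_material <- function(x, ...) {
  cat("Peridynamic membrane material\n")
  cat(sprintf("  K = %g MPa, G = %g MPa (nu = %.3f)\n",
              x$bulk_K, x$shear_G, poisson_ratio(x$bulk_K, x$shear_G)))
  cat(sprintf("  rho = %g kg/m^3 x %g (mass scaling)\n",
              x$density_rho, x$mass_scale))
  cat(sprintf("  critical stretch s_c = %g, contact c = %g\n",
              x$critical_stretch_sc, x$contact_scale_c))
  invisible(x)
}

#' Poisson's ratio of a 3D isotropic material
#'
#' `nu = (3K - 2G) / (2 (3K + G))`.  With K = 10 MPa this maps the shear
#' modulus range 0..10 MPa onto nu in 0.5..0.125, i.e. the transition from
#' an incompressible fluid film to a gel-like solid one.
#'
#' @param K Bulk modulus (same pressure unit as `G`).
#' @param G Shear modulus.
#' @return Dimensionless Poisson ratio in (-1, 0.5].
#' @examples
#' poisson_ratio(10, 0)    # 0.5, fluid limit
#' poisson_ratio(10, 10)   # 0.125
#' @export
poisson_ratio <- function(K, G) {
  stopifnot(K > 0, G >= 0)
  (3 * K - 2 * G) / (2 * (3 * K + G))
}

# material constants in internal units (um, s, kg); MPa is numerically 1
material_internal <- function(material, horizon) {
  Csr <- material$Csr_override
  if (is.null(Csr))
    Csr <- material$contact_scale_c * material$bulk_K * pi / horizon^5
  list(K = material$bulk_K,
       G = material$shear_G,
       critical_stretch = material$critical_stretch_sc,
       rho_internal = material$density_rho * material$mass_scale * 1e-18,
       Csr = Csr,
       contact_cutoff_mult = material$contact_cutoff_mult)
}

#' Weighted volume of material points
#'
#' Reference-configuration normalisation `m_i = sum_j omega |xi|^2 A_j` over
#' the initial bond set of particle i, with constant influence function
#' `omega = 1`.  Frozen at network construction: bond breaking enters the
#' force sums, not `m`.  An interior particle of a square lattice with
#' `h = 1` and `delta = 3` has `m = 136`.
#'
#' @param membrane A [build_circular_membrane()] object.
#' @param network A [build_bond_network()] object.
#' @param i Optional particle indices (default all).
#' @return Numeric vector of weighted volumes (um^4).  Isolated particles
#'   (no bonds) get 0 and are excluded from force evaluation.
#' @export
weighted_volume <- function(membrane, network, i = NULL) {
  stopifnot(inherits(membrane, "pd_membrane"),
            inherits(network, "pd_bond_network"))
  A <- membrane$area_per_particle
  src <- bond_sources(network)
  m <- rep(0, network$n_particles)
  s <- rowsum(network$ref_lengths^2 * A, src)
  m[as.integer(rownames(s))] <- s[, 1]
  if (is.null(i)) m else m[i]
}

#' Nonlocal dilatation
#'
#' 2D dilatation `theta_i = (2 / m_i) sum_j omega |xi| e A_j` over intact
#' bonds, with bond extension `e = |y_j - y_i| - |xi|`.  Depends on deformed
#' bond lengths only, hence invariant under rigid motions; equals `tr(eps)`
#' for uniform small strain (e.g. `2 s` under isotropic expansion by `s`).
#'
#' @param positions Current particle positions, N x 2 matrix (um).
#' @param membrane,network Discretisation objects.
#' @param i Optional particle indices (default all).
#' @return Numeric vector of dilatations (dimensionless).
#' @export
dilatation <- function(positions, membrane, network, i = NULL) {
  stopifnot(inherits(membrane, "pd_membrane"),
            inherits(network, "pd_bond_network"))
  positions <- as.matrix(positions)
  A <- membrane$area_per_particle
  src <- bond_sources(network)
  jdx <- network$bj + 1L
  keep <- network$intact
  d <- sqrt((positions[jdx, 1] - positions[src, 1])^2 +
            (positions[jdx, 2] - positions[src, 2])^2)
  e <- d - network$ref_lengths
  contrib <- ifelse(keep, network$ref_lengths * e * A, 0)
  th <- rep(0, network$n_particles)
  s <- rowsum(contrib, src)
  th[as.integer(rownames(s))] <- s[, 1]
  m <- weighted_volume(membrane, network)
  th <- ifelse(m > 0, 2 * th / m, 0)
  if (is.null(i)) th else th[i]
}

#' Per-bond scalar force states of the LPS membrane model
#'
#' Computes, for every intact directed bond, the scalar force state
#' `t = (2 K / m) theta |xi| + (8 G / m) (e - theta |xi| / 2)` evaluated at
#' the source particle.  This is a plain-R reference path used by the patch
#' test and as an independent cross-check of the compiled force kernel.
#'
#' @inheritParams dilatation
#' @param material A [material_model()] object.
#' @return A data frame with columns `i`, `j` (1-based), `t` (MPa / um^4),
#'   `e`, `ref_length`, and unit direction `ux`, `uy` along the deformed
#'   bond.
#' @export
bond_force_states <- function(positions, membrane, network, material) {
  stopifnot(inherits(material, "pd_material"))
  positions <- as.matrix(positions)
  src <- bond_sources(network)
  jdx <- network$bj + 1L
  dx <- positions[jdx, 1] - positions[src, 1]
  dy <- positions[jdx, 2] - positions[src, 2]
  d <- sqrt(dx^2 + dy^2)
  e <- d - network$ref_lengths
  th <- dilatation(positions, membrane, network)
  m <- weighted_volume(membrane, network)
  K <- material$bulk_K; G <- material$shear_G
  # the 1/eps factor mirrors the 3D->2D reduction of the weighted volume
  # (m_3D = eps m_2D) and cancels the thickness in the equation of motion
  tt <- (2 * K * th[src] * network$ref_lengths +
         8 * G * (e - 0.5 * th[src] * network$ref_lengths)) /
        (m[src] * membrane$thickness_eps)
  tt[!network$intact] <- 0
  ok <- d > 1e-12
  data.frame(i = src, j = jdx, t = tt, e = e,
             ref_length = network$ref_lengths,
             ux = ifelse(ok, dx / d, 0), uy = ifelse(ok, dy / d, 0))
}

#' Internal LPS force density
#'
#' Assembles the per-particle internal force density (MPa / um) from the
#' scalar force states, pairwise, so the total over a free body sums to zero
#' at machine precision.  Broken bonds contribute exactly zero; a bond whose
#' deformed length vanishes is skipped for the step (its direction is
#' undefined; the short-range machinery handles the overlap).
#'
#' @inheritParams bond_force_states
#' @return N x 2 matrix of force densities.
#' @export
internal_force_density <- function(positions, membrane, network, material) {
  eng <- pd_engine(membrane, network, material)
  cpp_engine_force(eng, as.matrix(positions), TRUE, FALSE)
}

#' Short-range repulsive contact force density
#'
#' Repulsion `f = min(0, C_sr (|y_j - y_i| - d_pi)) u_ij` with interaction
#' distance `d_pi = min(0.9 |x_j - x_i|, 1.35 h)`, applied between all
#' particle pairs in range (bonded or not) over the current configuration.
#' It prevents unphysical interpenetration; the force is identically zero at
#' separations of `1.35 h` and beyond.  Exactly coincident particles repel
#' along +x (deterministically).
#'
#' @inheritParams bond_force_states
#' @return N x 2 matrix of force densities (MPa / um).
#' @export
short_range_force <- function(positions, membrane, network, material) {
  eng <- pd_engine(membrane, network, material)
  cpp_engine_force(eng, as.matrix(positions), FALSE, TRUE)
}

#' Break bonds stretched beyond the critical stretch
#'
#' Marks every intact bond with stretch
#' `s = (|y_j - y_i| - |xi|) / |xi| > s_c` as broken, both directions at
#' once, irreversibly.  Compressed bonds (`s < 0`) never break.  Evaluated
#' once per accepted time step in the driver.
#'
#' @inheritParams bond_force_states
#' @return The network with updated `intact` flags and an attribute
#'   `newly_broken` (number of particle pairs newly broken).
#' @export
update_broken_bonds <- function(positions, network, material) {
  stopifnot(inherits(network, "pd_bond_network"),
            inherits(material, "pd_material"))
  positions <- as.matrix(positions)
  src <- bond_sources(network)
  jdx <- network$bj + 1L
  d <- sqrt((positions[jdx, 1] - positions[src, 1])^2 +
            (positions[jdx, 2] - positions[src, 2])^2)
  stretch <- (d - network$ref_lengths) / network$ref_lengths
  newly <- network$intact & (stretch > material$critical_stretch_sc)
  # symmetric by construction (stretch of (i,j) equals that of (j,i))
  network$intact[newly] <- FALSE
  attr(network, "newly_broken") <- sum(newly) / 2
  network
}

#' Per-particle damage
#'
#' `phi_i` is the fraction of particle i's initial bonds now broken; 100 %
#' damage means every bond of the material point is gone and the particle is
#' fully disconnected.  A particle that never had bonds is reported as fully
#' damaged (`phi = 1`).
#'
#' @param network A [build_bond_network()] object (after any bond breaking).
#' @return Numeric vector of damage fractions in `[0, 1]`.
#' @export
damage_field <- function(network) {
  stopifnot(inherits(network, "pd_bond_network"))
  src <- bond_sources(network)
  broken <- rep(0, network$n_particles)
  s <- rowsum(as.numeric(!network$intact), src)
  broken[as.integer(rownames(s))] <- s[, 1]
  n0 <- network$initial_bond_count
  ifelse(n0 > 0, broken / n0, 1)
}

# Build (or fetch a cached) compiled engine for a membrane/network/material
# triple.  The cache key is identity-based via an environment on the network.
pd_engine <- function(membrane, network, material, loading_rate = 0) {
  pinned <- seq_len(network$n_particles) %in% membrane$pinned_ids
  blayer <- seq_len(network$n_particles) %in% membrane$boundary_layer_ids
  eng <- cpp_engine_create(
    membrane$positions_ref,
    list(bptr = network$bptr, bj = network$bj, brev = network$brev,
         blen = network$ref_lengths),
    pinned, blayer,
    material_internal(material, network$horizon_delta),
    membrane$spacing_h, membrane$thickness_eps, loading_rate,
    membrane$diameter_0,
    membrane$diameter_0 / 2 - membrane$layer_width)
  # replay already-broken bonds so the engine matches the R-side network
  if (!all(network$intact)) cpp_engine_sync_intact(eng, network$intact)
  eng
}
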