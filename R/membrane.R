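#' Build a circular particle discretisation of the distal bilayer
#'
#' Places material points on a square lattice of spacing `spacing` and keeps
#' every point within `diameter / 2` of the origin (closed disc).  Each point
#' represents an area `spacing^2` of membrane of thickness `thickness`.
#' Points within `layer_width` of the outer edge form the boundary loading
#' layer; driving this layer, rather than the rim points themselves,
#' mitigates unphysical boundary fracture caused by the bond deficit at the
#' free edge.
#'
#' Defaults follow the study conditions for the full-scale membrane: a
#' 200 um diameter disc, 1 um spacing, 5 nm (0.005 um) thickness and a
#' 10 um loading layer.
#'
#' @param diameter Initial membrane diameter D0 (um).
#' @param spacing Lattice spacing h (um).
#' @param thickness Membrane thickness (um).
#' @param layer_width Width of the driven boundary layer (um).
#' @return An object of class `pd_membrane`: a list with `positions_ref`
#'   (N x 2 matrix, um), `spacing_h`, `thickness_eps`, `area_per_particle`,
#'   `diameter_0`, `layer_width`, `boundary_layer_ids` and `pinned_ids`.
#' @examples
#' m <- build_circular_membrane(diameter = 20, spacing = 1)
#' nrow(m$positions_ref)
#' @export
build_circular_membrane <- function(diameter = 200, spacing = 1,
                                    thickness = 0.005, layer_width = 10) {
  if (!is.numeric(diameter) || length(diameter) != 1L || diameter <= 0)
    stop("configuration error: 'diameter' must be a positive length", call. = FALSE)
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0 ||
      spacing >= diameter)
    stop("configuration error: 'spacing' must satisfy 0 < spacing < diameter",
         call. = FALSE)
  if (!is.numeric(thickness) || length(thickness) != 1L || thickness <= 0)
    stop("configuration error: 'thickness' must be a positive length", call. = FALSE)
  if (!is.numeric(layer_width) || length(layer_width) != 1L || layer_width <= 0)
    stop("configuration error: 'layer_width' must be a positive length", call. = FALSE)

  r <- diameter / 2
  imax <- floor(r / spacing)
  idx <- seq.int(-imax, imax)
  grid <- expand.grid(i = idx, j = idx)
  # integer-lattice radius test so points exactly on the rim are kept
  keep <- (grid$i^2 + grid$j^2) * spacing^2 <= r^2 * (1 + 1e-12)
  pos <- cbind(x = grid$i[keep] * spacing, y = grid$j[keep] * spacing)
  rad <- sqrt(pos[, 1]^2 + pos[, 2]^2)
  boundary_layer_ids <- which(rad > r - layer_width)

  structure(list(
    positions_ref = pos,
    spacing_h = spacing,
    thickness_eps = thickness,
    area_per_particle = spacing^2,
    diameter_0 = diameter,
    layer_width = layer_width,
    boundary_layer_ids = as.integer(boundary_layer_ids),
    pinned_ids = integer(0)
  ), class = "pd_membrane")
}

#' @export
print.pd_membrane <- function(x, ...) {
  cat("Peridynamic membrane discretisation\n")
  cat(sprintf("  particles     : %d\n", nrow(x$positions_ref)))
  cat(sprintf("  diameter D0   : %g um, spacing h: %g um, thickness: %g um\n",
              x$diameter_0, x$spacing_h, x$thickness_eps))
  cat(sprintf("  boundary layer: %d particles (width %g um)\n",
              length(x$boundary_layer_ids), x$layer_width))
  cat(sprintf("  pinned        : %d particles\n", length(x$pinned_ids)))
  invisible(x)
}

#' @export
plot.pd_membrane <- function(x, ...) {
  pos <- x$positions_ref
  col <- rep("grey60", nrow(pos))
  col[x$boundary_layer_ids] <- "steelblue"
  col[x$pinned_ids] <- "red"
  plot(pos, asp = 1, pch = 16, cex = 0.4, col = col,
       xlab = "x (um)", ylab = "y (um)", ...)
  invisible(x)
}

#' Build the horizon-based bond network
#'
#' Connects every pair of particles whose reference distance lies in
#' `(0, horizon]` (closed ball, so lattice points at exactly the horizon are
#' bonded).  The returned network stores directed bonds in compressed sparse
#' row layout together with the reverse-bond index, reference lengths, intact
#' flags and the initial per-particle bond count used by [damage_field()].
#'
#' @param membrane A [build_circular_membrane()] object.
#' @param horizon Neighbourhood radius delta (um); must be at least the
#'   lattice spacing or no bonds are possible.
#' @return An object of class `pd_bond_network`.
#' @examples
#' m <- build_circular_membrane(diameter = 20, spacing = 1)
#' net <- build_bond_network(m, horizon = 3)
#' @export
build_bond_network <- function(membrane, horizon = 3) {
  stopifnot(inherits(membrane, "pd_membrane"))
  if (!is.numeric(horizon) || length(horizon) != 1L ||
      horizon < membrane$spacing_h)
    stop("configuration error: 'horizon' must be >= the lattice spacing ",
         "(no bonds possible otherwise)", call. = FALSE)
  b <- cpp_build_bonds(membrane$positions_ref, horizon)
  n <- nrow(membrane$positions_ref)
  structure(list(
    horizon_delta = horizon,
    bptr = b$bptr,            # 0-based CSR pointers, length n + 1
    bj = b$bj,                # 0-based neighbour indices
    brev = b$brev,            # index of the reverse directed bond (0-based)
    ref_lengths = b$blen,
    intact = rep(TRUE, length(b$bj)),
    initial_bond_count = as.integer(diff(b$bptr)),
    n_particles = n
  ), class = "pd_bond_network")
}

#' Neighbour indices of one particle
#'
#' @param network A [build_bond_network()] object.
#' @param i Particle index (1-based).
#' @param intact_only Drop broken bonds?
#' @return Integer vector of 1-based neighbour indices.
#' @export
bond_neighbors <- function(network, i, intact_only = FALSE) {
  stopifnot(inherits(network, "pd_bond_network"))
  rng <- bond_range(network, i)
  if (length(rng) == 0L) return(integer(0))
  j <- network$bj[rng] + 1L
  if (intact_only) j <- j[network$intact[rng]]
  j
}

# 1-based positions in the flat bond arrays belonging to particle i
bond_range <- function(network, i) {
  lo <- network$bptr[i] + 1L
  hi <- network$bptr[i + 1L]
  if (hi < lo) integer(0) else seq.int(lo, hi)
}

# source particle (1-based) of every directed bond
bond_sources <- function(network) {
  rep.int(seq_len(network$n_particles), diff(network$bptr))
}

#' @export
print.pd_bond_network <- function(x, ...) {
  cat("Peridynamic bond network\n")
  cat(sprintf("  horizon delta : %g um\n", x$horizon_delta))
  cat(sprintf("  particles     : %d\n", x$n_particles))
  cat(sprintf("  directed bonds: %d (%d intact)\n",
              length(x$bj), sum(x$intact)))
  invisible(x)
}

#' Choose pinning sites on the membrane
#'
#' Selects `n` distinct interior particles to be held fixed for the whole
#' simulation; in the physical system these correspond to Ca2+-mediated
#' interconnections between the distal and proximal bilayers, and they act as
#' rupture nucleation sites.  Sites are drawn uniformly over the interior
#' disc (radius `diameter/2 - layer_width`), or over `region` when given (to
#' reproduce clustered-pin layouts); an explicit `coordinates` matrix
#' overrides sampling entirely, with each coordinate mapped to the nearest
#' lattice particle (ties broken by lowest particle index).  Random draws
#' that land in the boundary loading layer or on an already chosen particle
#' are resampled, so pins and driven particles never coincide.
#'
#' @param membrane A [build_circular_membrane()] object.
#' @param n Number of pinning sites.
#' @param seed Integer seed; the same (n, seed, region) always reproduces the
#'   same pinning set.
#' @param region Optional disc `list(center = c(x, y), radius = r)` restricting
#'   placement.
#' @param coordinates Optional n x 2 matrix of explicit pin coordinates (um).
#' @return An object of class `pd_pinning`: list with `ids` (particle
#'   indices), `coordinates`, `n`, `seed`.
#' @export
assign_pinning <- function(membrane, n, seed = 1L, region = NULL,
                           coordinates = NULL) {
  stopifnot(inherits(membrane, "pd_membrane"))
  pos <- membrane$positions_ref
  interior <- setdiff(seq_len(nrow(pos)), membrane$boundary_layer_ids)

  if (!is.null(coordinates)) {
    coordinates <- as.matrix(coordinates)
    stopifnot(ncol(coordinates) == 2L)
    ids <- integer(nrow(coordinates))
    for (k in seq_len(nrow(coordinates))) {
      d2 <- (pos[, 1] - coordinates[k, 1])^2 + (pos[, 2] - coordinates[k, 2])^2
      ids[k] <- which(d2 == min(d2))[1L]   # tie -> lowest index
    }
    if (anyDuplicated(ids))
      stop("pinning coordinates map to duplicate particles", call. = FALSE)
    if (any(ids %in% membrane$boundary_layer_ids))
      stop("explicit pinning coordinate falls in the boundary loading layer",
           call. = FALSE)
    return(structure(list(ids = ids, coordinates = pos[ids, , drop = FALSE],
                          n = length(ids), seed = NA_integer_),
                     class = "pd_pinning"))
  }

  if (!is.numeric(n) || length(n) != 1L || n < 0)
    stop("'n' must be a non-negative count", call. = FALSE)
  n <- as.integer(n)
  if (n > length(interior))
    stop("n exceeds the number of non-boundary-layer particles", call. = FALSE)
  if (n == 0L)
    return(structure(list(ids = integer(0),
                          coordinates = pos[integer(0), , drop = FALSE],
                          n = 0L, seed = as.integer(seed)),
                     class = "pd_pinning"))

  r_int <- membrane$diameter_0 / 2 - membrane$layer_width
  if (is.null(region)) region <- list(center = c(0, 0), radius = r_int)
  stopifnot(is.list(region), length(region$center) == 2L, region$radius > 0)

  ids <- with_seed(seed, {
    chosen <- integer(0)
    guard <- 0L
    while (length(chosen) < n) {
      guard <- guard + 1L
      if (guard > 10000L)
        stop("could not place pinning sites in the requested region",
             call. = FALSE)
      # uniform over the disc region, then snap to the nearest lattice point
      rad <- region$radius * sqrt(runif(1))
      ang <- runif(1) * 2 * pi
      p <- region$center + rad * c(cos(ang), sin(ang))
      i <- round(p[1] / membrane$spacing_h)
      j <- round(p[2] / membrane$spacing_h)
      d2 <- (pos[, 1] - i * membrane$spacing_h)^2 +
            (pos[, 2] - j * membrane$spacing_h)^2
      id <- which(d2 == min(d2))[1L]
      if (id %in% chosen) next
      if (id %in% membrane$boundary_layer_ids) next   # never pin the driven rim
      if (sqrt(sum(pos[id, ]^2)) > r_int) next
      if (sqrt(sum((pos[id, ] - region$center)^2)) > region$radius) next
      chosen <- c(chosen, id)
    }
    chosen
  })

  structure(list(ids = as.integer(ids),
                 coordinates = pos[ids, , drop = FALSE],
                 n = n, seed = as.integer(seed)),
            class = "pd_pinning")
}

#' @export
print.pd_pinning <- function(x, ...) {
  cat(sprintf("Pinning set: %d sites (seed %s)\n", x$n,
              ifelse(is.na(x$seed), "explicit", x$seed)))
  invisible(x)
}

#' Attach a pinning set to a membrane
#'
#' @param membrane A [build_circular_membrane()] object.
#' @param pinning A [assign_pinning()] object (or integer particle indices).
#' @return The membrane with `pinned_ids` set (boundary-layer membership is
#'   removed from pinned particles so a pinned particle is never driven).
#' @export
set_pinning <- function(membrane, pinning) {
  stopifnot(inherits(membrane, "pd_membrane"))
  ids <- if (inherits(pinning, "pd_pinning")) pinning$ids else as.integer(pinning)
  membrane$pinned_ids <- ids
  membrane$boundary_layer_ids <- setdiff(membrane$boundary_layer_ids, ids)
  membrane
}

# evaluate expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
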