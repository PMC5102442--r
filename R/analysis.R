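#' Rasterise the rupture contour of a snapshot
#'
#' Builds a binary image of the rupture pattern.  The occupied region is the
#' union of discs (radius `fill_radius`, default 0.75 h so the square
#' lattice tiles without gaps) around particles whose damage is below
#' `damage_threshold`; the void is the complement within the convex hull of
#' all particles; the mask is the set of contour pixels of the void.  The
#' outer rim contour — the contour component adjacent to the hull boundary,
#' i.e. the expanding membrane edge — is removed automatically, replacing
#' the manual image editing step with a reproducible rule.
#'
#' @param snapshot A trajectory snapshot (`positions` + `damage`), or a list
#'   with those fields.
#' @param spacing Lattice spacing h (um), used for the fill radius default.
#' @param resolution Pixel size (um/px); default 0.5 um/px, two pixels per
#'   particle spacing.
#' @param damage_threshold Particles at or above this damage no longer
#'   occupy material (default 0.5).
#' @param fill_radius Disc radius around intact particles (um).
#' @param remove_rim Drop the hull-touching contour component?
#' @return An object of class `pd_rupture_mask`: list with `mask` (logical
#'   matrix, rows = y, cols = x), `void` (logical matrix), `origin` (um
#'   coordinates of pixel [1,1] centre), `resolution`, `rim_removed`,
#'   `in_hull`.  The mask is empty (flagged `empty = TRUE`) for an
#'   undamaged membrane.
#' @export
rasterize_rupture <- function(snapshot, spacing = 1, resolution = 0.5,
                              damage_threshold = 0.5,
                              fill_radius = 0.75 * spacing,
                              remove_rim = TRUE) {
  pos <- as.matrix(snapshot$positions)
  dmg <- snapshot$damage
  stopifnot(length(dmg) == nrow(pos))

  pad <- 2 * resolution
  xr <- range(pos[, 1]) + c(-pad, pad)
  yr <- range(pos[, 2]) + c(-pad, pad)
  nx <- max(8L, ceiling(diff(xr) / resolution))
  ny <- max(8L, ceiling(diff(yr) / resolution))
  xs <- xr[1] + (seq_len(nx) - 0.5) * resolution
  ys <- yr[1] + (seq_len(ny) - 0.5) * resolution

  # pixels inside the convex hull of all particles
  hull <- grDevices::chull(pos)
  bnd <- pos[hull, , drop = FALSE]
  px <- rep(xs, each = ny)
  py <- rep(ys, times = nx)
  inside <- mgcv::in.out(rbind(bnd, bnd[1, ]), cbind(px, py))
  in_hull <- matrix(inside, nrow = ny, ncol = nx)

  # occupied = union of discs at particles that still carry material
  occ <- matrix(FALSE, ny, nx)
  alive <- which(dmg < damage_threshold)
  rpx <- ceiling(fill_radius / resolution)
  for (i in alive) {
    cx <- round((pos[i, 1] - xs[1]) / resolution) + 1
    cy <- round((pos[i, 2] - ys[1]) / resolution) + 1
    ix <- max(1, cx - rpx):min(nx, cx + rpx)
    iy <- max(1, cy - rpx):min(ny, cy + rpx)
    dx2 <- (xs[ix] - pos[i, 1])^2
    dy2 <- (ys[iy] - pos[i, 2])^2
    hit <- outer(dy2, dx2, "+") <= fill_radius^2
    occ[iy, ix] <- occ[iy, ix] | hit
  }

  void <- in_hull & !occ

  # contour = void pixels with a non-void 4-neighbour (or hull/image edge)
  contour <- void & !shift_all4(void)

  rim_removed <- FALSE
  if (remove_rim && any(contour)) {
    lab <- cpp_label8(contour)
    # rim components touch a pixel outside the hull (or the image edge)
    outside <- !in_hull
    edge <- matrix(FALSE, ny, nx)
    edge[1, ] <- TRUE; edge[ny, ] <- TRUE; edge[, 1] <- TRUE; edge[, nx] <- TRUE
    touch <- dilate8(outside | edge)
    rim_labels <- unique(lab[contour & touch])
    if (length(rim_labels)) {
      contour[lab %in% rim_labels] <- FALSE
      rim_removed <- TRUE
    }
  }

  structure(list(mask = contour, void = void, in_hull = in_hull,
                 origin = c(xs[1], ys[1]), resolution = resolution,
                 rim_removed = rim_removed, empty = !any(contour)),
            class = "pd_rupture_mask")
}

# TRUE where all 4-neighbours (clipped at the border) are TRUE
shift_all4 <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  up <- rbind(m[-1, , drop = FALSE], FALSE)
  dn <- rbind(FALSE, m[-ny, , drop = FALSE])
  lf <- cbind(m[, -1, drop = FALSE], FALSE)
  rt <- cbind(FALSE, m[, -nx, drop = FALSE])
  up & dn & lf & rt
}

# 8-neighbourhood dilation (including the pixel itself)
dilate8 <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  out <- m
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    src_r <- max(1, 1 - dy):min(ny, ny - dy)
    dst_r <- src_r + dy
    src_c <- max(1, 1 - dx):min(nx, nx - dx)
    dst_c <- src_c + dx
    out[dst_r, dst_c] <- out[dst_r, dst_c] | m[src_r, src_c]
  }
  out
}

#' @export
print.pd_rupture_mask <- function(x, ...) {
  cat(sprintf(
    "Rupture mask: %d x %d px at %g um/px, %d contour pixels%s%s\n",
    ncol(x$mask), nrow(x$mask), x$resolution, sum(x$mask),
    if (x$rim_removed) ", rim removed" else "",
    if (x$empty) " (empty)" else ""))
  invisible(x)
}

#' @export
plot.pd_rupture_mask <- function(x, ...) {
  graphics::image(t(x$mask), col = c("white", "black"), asp = nrow(x$mask) /
                    ncol(x$mask), axes = FALSE, ...)
  invisible(x)
}

#' Detect pores in a rupture mask
#'
#' 8-connected components of the void raster, excluding the exterior (any
#' component that touches the region outside the convex hull or the image
#' edge).  Areas are reported in um^2.
#'
#' @param mask A [rasterize_rupture()] object.
#' @param min_area_px Drop components smaller than this many pixels
#'   (speckle guard, default 4).
#' @param region_radius Optional radius (um, about the origin): keep only
#'   pores whose centroid lies inside it.  Used to separate interior pores
#'   from the void arcs left behind by the detaching driven rim, mirroring
#'   the rim-removal rule of the contour mask.
#' @return Data frame with one row per pore: `id`, `area` (um^2),
#'   `centroid_x`, `centroid_y` (um).
#' @export
detect_pores <- function(mask, min_area_px = 4, region_radius = NULL) {
  stopifnot(inherits(mask, "pd_rupture_mask"))
  void <- mask$void
  if (!any(void))
    return(data.frame(id = integer(0), area = numeric(0),
                      centroid_x = numeric(0), centroid_y = numeric(0)))
  lab <- cpp_label8(void)
  ny <- nrow(void); nx <- ncol(void)
  edge <- matrix(FALSE, ny, nx)
  edge[1, ] <- TRUE; edge[ny, ] <- TRUE; edge[, 1] <- TRUE; edge[, nx] <- TRUE
  touch <- dilate8(!mask$in_hull | edge)
  exterior_labels <- unique(lab[void & touch])
  keep <- setdiff(seq_len(attr(lab, "n_components")), exterior_labels)
  res <- mask$resolution
  rows <- lapply(keep, function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    if (nrow(idx) < min_area_px) return(NULL)
    data.frame(id = k, area = nrow(idx) * res^2,
               centroid_x = mask$origin[1] + (mean(idx[, 2]) - 1) * res,
               centroid_y = mask$origin[2] + (mean(idx[, 1]) - 1) * res)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(id = integer(0), area = numeric(0),
                      centroid_x = numeric(0), centroid_y = numeric(0))
  if (!is.null(region_radius) && nrow(out))
    out <- out[sqrt(out$centroid_x^2 + out$centroid_y^2) <= region_radius, ,
               drop = FALSE]
  out$id <- seq_len(nrow(out))
  out
}

#' Box-counting fractal dimension
#'
#' Covers the image with grids of square boxes (sizes default to powers of
#' two from 2 px up to a quarter of the shorter image side, grid anchored at
#' the image origin), counts boxes containing at least one mask pixel, and
#' fits `log(count)` against `log(size)` by least squares; the fractal
#' dimension is minus the slope.
#'
#' @param mask A [rasterize_rupture()] object, or a logical matrix.
#' @param sizes Box sizes in pixels (default powers of 2).
#' @return An object of class `pd_boxcount`: list with `sizes`, `counts`,
#'   `D`, `intercept`, `r_squared`.  Errors on an empty mask or fewer than
#'   3 usable sizes; warns when the log-log fit has R^2 < 0.95.
#' @examples
#' m <- make_fractal_raster("sierpinski", level = 5, size = 128)
#' box_count_dimension(m)$D
#' @export
box_count_dimension <- function(mask, sizes = NULL) {
  m <- if (inherits(mask, "pd_rupture_mask")) mask$mask else as.matrix(mask)
  mode(m) <- "logical"
  if (!any(m))
    stop("box counting refused: the mask is empty", call. = FALSE)
  side <- min(dim(m))
  if (is.null(sizes)) {
    smax <- side %/% 4
    sizes <- 2^(1:floor(log2(max(smax, 2))))
    sizes <- sizes[sizes <= smax]
  }
  sizes <- sort(unique(as.integer(sizes)))
  sizes <- sizes[sizes >= 1 & sizes <= side]
  if (length(sizes) < 3)
    stop("box counting needs at least 3 usable box sizes", call. = FALSE)
  pix <- which(m, arr.ind = TRUE)
  counts <- vapply(sizes, function(s) {
    bx <- (pix[, 1] - 1L) %/% s
    by <- (pix[, 2] - 1L) %/% s
    length(unique(bx + by * (nrow(m) %/% s + 2L)))
  }, numeric(1))
  fit <- lm(log(counts) ~ log(sizes))
  # summary.lm warns on an exactly collinear fit (line/square validators)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (is.na(r2)) r2 <- 0
  if (r2 < 0.95)
    warning(sprintf("box-count fit is poor (R^2 = %.3f)", r2), call. = FALSE)
  structure(list(sizes = sizes, counts = counts,
                 D = -unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]), r_squared = r2),
            class = "pd_boxcount")
}

#' @export
print.pd_boxcount <- function(x, ...) {
  cat(sprintf("Box-counting fit: D = %.3f (R^2 = %.4f, %d sizes %d..%d px)\n",
              x$D, x$r_squared, length(x$sizes), min(x$sizes), max(x$sizes)))
  invisible(x)
}

#' @export
plot.pd_boxcount <- function(x, ...) {
  plot(log(x$sizes), log(x$counts), pch = 16,
       xlab = "log box size (px)", ylab = "log occupied boxes",
       main = sprintf("D = %.3f", x$D), ...)
  graphics::abline(x$intercept, -x$D, col = "red")
  invisible(x)
}

#' Morphology report over a trajectory
#'
#' Per-snapshot rupture metrics: pore count, total void area, box-counting
#' dimension of the rupture contour and the expansion ratio.  The final
#' snapshot's D is the headline morphology statistic; the attached
#' floral/fractal label (D below/above `label_threshold`) is a convenience
#' only — quantitative comparisons should use D itself.
#'
#' @param trajectory A [run_simulation()] result.
#' @param resolution Raster resolution (um/px).
#' @param damage_threshold Damage cut for void particles.
#' @param label_threshold D threshold separating the convenience labels.
#' @param snapshots Snapshot indices to analyse (default: all).
#' @return An object of class `pd_morphology`: data frame with columns `t`,
#'   `ratio`, `n_pores`, `void_area`, `D`, `r_squared`, `label`; empty with
#'   a note when no snapshot shows rupture.
#' @export
morphology_report <- function(trajectory, resolution = 0.5,
                              damage_threshold = 0.5, label_threshold = 1.4,
                              snapshots = NULL) {
  stopifnot(inherits(trajectory, "pd_trajectory"))
  idx <- snapshots %||% seq_along(trajectory$snapshots)
  h <- trajectory$config$spacing
  rows <- lapply(idx, function(k) {
    s <- trajectory$snapshots[[k]]
    mk <- rasterize_rupture(s, spacing = h, resolution = resolution,
                            damage_threshold = damage_threshold)
    pores <- detect_pores(mk)
    D <- NA_real_; r2 <- NA_real_
    if (!mk$empty) {
      bc <- tryCatch(suppressWarnings(box_count_dimension(mk)),
                     error = function(e) NULL)
      if (!is.null(bc)) { D <- bc$D; r2 <- bc$r_squared }
    }
    data.frame(snapshot = k, t = s$t, ratio = s$ratio,
               n_pores = nrow(pores), void_area = sum(pores$area),
               D = D, r_squared = r2,
               label = if (is.na(D)) NA_character_ else
                 if (D < label_threshold) "floral-like" else "fractal-like")
  })
  out <- do.call(rbind, rows)
  if (all(is.na(out$D)))
    attr(out, "note") <- "no rupture detected in any analysed snapshot"
  class(out) <- c("pd_morphology", class(out))
  out
}

#' @export
print.pd_morphology <- function(x, ...) {
  cat("Rupture morphology report\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  if (!is.null(attr(x, "note"))) cat("note:", attr(x, "note"), "\n")
  invisible(x)
}
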