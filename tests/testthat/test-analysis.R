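# helper: synthetic snapshot of an intact disc with circular holes punched
# (damage = 1 inside the holes)
synthetic_holey_snapshot <- function(diameter = 40, holes = list()) {
  m <- build_circular_membrane(diameter = diameter, spacing = 1)
  dmg <- rep(0, nrow(m$positions_ref))
  for (hl in holes) {
    d2 <- (m$positions_ref[, 1] - hl$center[1])^2 +
          (m$positions_ref[, 2] - hl$center[2])^2
    dmg[d2 <= hl$radius^2] <- 1
  }
  list(positions = m$positions_ref, damage = dmg, t = 0, ratio = 1)
}

test_that("an undamaged membrane yields an empty mask that box counting refuses", {
  s <- synthetic_holey_snapshot(40)
  mk <- rasterize_rupture(s)
  expect_true(mk$empty)
  expect_equal(sum(mk$mask), 0)
  expect_error(box_count_dimension(mk), "empty")
})

test_that("the contour of a circular hole has the expected length and survives rim removal", {
  s <- synthetic_holey_snapshot(40, list(list(center = c(0, 0), radius = 6)))
  mk <- rasterize_rupture(s, resolution = 0.5)
  expect_false(mk$empty)
  # the hull-touching outer contour was dropped, the hole contour kept
  expect_true(mk$rim_removed)
  # contour pixel count approximates the circumference 2 pi r / resolution;
  # 8-connected marching overcounts slightly, so compare within 15 percent
  r_eff <- 6 + 0.75  # hole radius plus the particle fill radius
  expected <- 2 * pi * r_eff / 0.5
  expect_lt(abs(sum(mk$mask) - expected) / expected, 0.15)
  # every contour pixel sits near the hole edge, not at the rim
  px <- which(mk$mask, arr.ind = TRUE)
  xs <- mk$origin[1] + (px[, 2] - 1) * mk$resolution
  ys <- mk$origin[2] + (px[, 1] - 1) * mk$resolution
  expect_lt(max(sqrt(xs^2 + ys^2)), 10)
})

test_that("pore detection counts disjoint holes and their merger", {
  two <- synthetic_holey_snapshot(40, list(
    list(center = c(-8, 0), radius = 4), list(center = c(8, 0), radius = 4)))
  p2 <- detect_pores(rasterize_rupture(two))
  expect_equal(nrow(p2), 2L)
  # centroids at the hole centres, areas near the punched pi r^2
  expect_equal(sort(p2$centroid_x), c(-8, 8), tolerance = 0.1)
  expect_equal(p2$area, rep(pi * 4^2, 2), tolerance = 0.15)

  # dilate the holes until they overlap: one merged pore
  merged <- synthetic_holey_snapshot(40, list(
    list(center = c(-8, 0), radius = 9), list(center = c(8, 0), radius = 9)))
  expect_equal(nrow(detect_pores(rasterize_rupture(merged))), 1L)

  # no damage, no pores
  none <- synthetic_holey_snapshot(40)
  expect_equal(nrow(detect_pores(rasterize_rupture(none))), 0L)
})

test_that("8-connected labeling matches hand enumeration", {
  mk <- matrix(FALSE, 5, 5)
  mk[1, 1] <- TRUE; mk[2, 2] <- TRUE   # diagonal touch: one component
  mk[5, 5] <- TRUE                     # far corner: second component
  lab <- perimem:::cpp_label8(mk)
  expect_equal(attr(lab, "n_components"), 2L)
  expect_equal(lab[1, 1], lab[2, 2])
  expect_true(lab[5, 5] != lab[1, 1])
})

test_that("box counting recovers analytic dimensions on validation rasters", {
  Dline <- box_count_dimension(make_fractal_raster("line", size = 512))$D
  expect_equal(Dline, 1, tolerance = 0.05)

  Dsq <- box_count_dimension(make_fractal_raster("square", size = 512))$D
  expect_equal(Dsq, 2, tolerance = 0.05)

  Dsp <- box_count_dimension(
    make_fractal_raster("sierpinski", level = 7, size = 512))$D
  expect_equal(Dsp, log(3) / log(2), tolerance = 0.05)
})

test_that("box counts equal the direct grid enumeration and behave monotonically", {
  mk <- make_fractal_raster("sierpinski", level = 5, size = 256)
  bc <- box_count_dimension(mk)
  for (k in seq_along(bc$sizes))
    expect_equal(bc$counts[k], oracle_box_count(mk$mask, bc$sizes[k]))
  expect_true(all(diff(bc$counts) <= 0))
  expect_gt(bc$r_squared, 0.99)
})

test_that("box-count dimension is stable under halving the raster resolution", {
  D512 <- box_count_dimension(
    make_fractal_raster("sierpinski", level = 7, size = 512))$D
  D256 <- box_count_dimension(
    make_fractal_raster("sierpinski", level = 7, size = 256))$D
  expect_lt(abs(D512 - D256), 0.05)
})

test_that("box counting validates its inputs", {
  mk <- make_fractal_raster("line", size = 512)
  expect_error(box_count_dimension(mk, sizes = c(2, 4)), "3 usable")
  # a sparse random dust gives a poor log-log fit and warns
  set.seed(1)
  dust <- matrix(runif(64 * 64) < 0.002, 64, 64)
  dust[1, 1] <- TRUE
  expect_warning(box_count_dimension(dust, sizes = c(2, 4, 8, 16)), "poor")
})

test_that("morphology report labels smooth and fractal patterns sensibly", {
  # single circular hole: D near 1, floral-like label
  s <- synthetic_holey_snapshot(40, list(list(center = c(0, 0), radius = 7)))
  mk <- rasterize_rupture(s)
  bc <- box_count_dimension(mk)
  expect_lt(bc$D, 1.4)

  # Sierpinski raster injected as a mask classifies as fractal-like
  Dsp <- box_count_dimension(
    make_fractal_raster("sierpinski", level = 7, size = 512))$D
  expect_gt(Dsp, 1.4)

  # report over a real scaled run: one row per snapshot, metrics populated
  traj <- nucleation_runs(seeds = 1)[[1]]
  rep <- morphology_report(traj)
  expect_equal(nrow(rep), length(traj$snapshots))
  expect_true(all(c("t", "ratio", "n_pores", "void_area", "D", "label")
                  %in% names(rep)))
  last <- rep[nrow(rep), ]
  expect_false(is.na(last$D))
  expect_true(last$label %in% c("floral-like", "fractal-like"))
  # a pristine trajectory reports no rupture
  rep0 <- morphology_report(traj, snapshots = 1)
  expect_true(is.na(rep0$D[1]))
  expect_match(attr(rep0, "note"), "no rupture")
})

test_that("masks export as 1-bit PNG", {
  mk <- make_fractal_raster("sierpinski", level = 4, size = 64)
  tf <- tempfile(fileext = ".png")
  write_mask_png(mk, tf)
  img <- png::readPNG(tf)
  expect_equal(dim(img)[1:2], c(64, 64))
  expect_equal(sum(img == 0), sum(mk$mask))
  unlink(tf)
})
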