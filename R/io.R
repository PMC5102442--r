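#' Write a snapshot as columnar text
#'
#' One row per particle: id, reference position, current position, velocity,
#' damage and the pinned / boundary-layer flags.  Plain whitespace-separated
#' text with a header line.
#'
#' @param snapshot A trajectory snapshot.
#' @param membrane The matching [build_circular_membrane()] object.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_snapshot <- function(snapshot, membrane, file) {
  n <- nrow(snapshot$positions)
  df <- data.frame(
    id = seq_len(n),
    x0 = membrane$positions_ref[, 1], y0 = membrane$positions_ref[, 2],
    x = snapshot$positions[, 1], y = snapshot$positions[, 2],
    vx = snapshot$velocities[, 1], vy = snapshot$velocities[, 2],
    damage = snapshot$damage,
    pinned = as.integer(seq_len(n) %in% membrane$pinned_ids),
    boundary = as.integer(seq_len(n) %in% membrane$boundary_layer_ids))
  write.table(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a columnar snapshot written by [write_snapshot()]
#'
#' @param file Input path.
#' @return A list with `positions`, `velocities`, `damage`, plus the raw
#'   data frame as `table`.
#' @export
read_snapshot <- function(file) {
  df <- read.table(file, header = TRUE)
  list(positions = cbind(df$x, df$y), velocities = cbind(df$vx, df$vy),
       damage = df$damage, table = df)
}

#' Write a snapshot as legacy VTK polydata
#'
#' ASCII legacy-format VTK polydata with the particles as vertices and
#' damage plus speed as point data, for visualisation in ParaView and
#' friends.
#'
#' @inheritParams write_snapshot
#' @export
write_vtk_polydata <- function(snapshot, membrane, file) {
  n <- nrow(snapshot$positions)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("membrane snapshot t=%g", snapshot$t),
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", n)), con)
  writeLines(sprintf("%g %g 0", snapshot$positions[, 1],
                     snapshot$positions[, 2]), con)
  writeLines(c(sprintf("VERTICES %d %d", n, 2 * n),
               sprintf("1 %d", seq_len(n) - 1L),
               sprintf("POINT_DATA %d", n),
               "SCALARS damage float 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%g", snapshot$damage), con)
  writeLines(c("SCALARS speed float 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%g", sqrt(snapshot$velocities[, 1]^2 +
                                snapshot$velocities[, 2]^2)), con)
  invisible(file)
}

#' Write a rupture mask as a 1-bit PNG
#'
#' @param mask A [rasterize_rupture()] object.
#' @param file Output path.
#' @export
write_mask_png <- function(mask, file) {
  stopifnot(inherits(mask, "pd_rupture_mask"))
  img <- 1 - mask$mask[rev(seq_len(nrow(mask$mask))), , drop = FALSE] * 1
  png::writePNG(img, file)
  invisible(file)
}
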