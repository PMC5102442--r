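# Brute-force oracles, independent of the package's lattice and bond code.

# integer lattice points (i*h, j*h) inside a closed disc of given diameter
oracle_disc_count <- function(diameter, h = 1) {
  imax <- floor(diameter / (2 * h))
  r2 <- (diameter / (2 * h))^2
  cnt <- 0L
  for (i in -imax:imax) for (j in -imax:imax)
    if (i^2 + j^2 <= r2) cnt <- cnt + 1L
  cnt
}

# square-lattice offsets with 0 < |xi| <= delta (h = 1)
oracle_offsets <- function(delta) {
  k <- ceiling(delta)
  out <- NULL
  for (i in -k:k) for (j in -k:k) {
    if (i == 0 && j == 0) next
    if (i^2 + j^2 <= delta^2 + 1e-9) out <- rbind(out, c(i, j))
  }
  out
}

# weighted volume of an interior particle: sum |xi|^2 * A over offsets
oracle_weighted_volume <- function(delta, h = 1) {
  off <- oracle_offsets(delta / h)
  sum((off[, 1]^2 + off[, 2]^2) * h^2) * h^2
}

# closed-form harmonic oscillator y(t) = cos(omega t) for y0 = 1, v0 = 0
oracle_oscillator <- function(omega, t) cos(omega * t)

# box counts of a pixel set by direct grid enumeration
oracle_box_count <- function(mask, size) {
  pix <- which(mask, arr.ind = TRUE)
  length(unique(paste((pix[, 1] - 1L) %/% size, (pix[, 2] - 1L) %/% size)))
}
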