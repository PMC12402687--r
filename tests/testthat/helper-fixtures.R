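# fixtures are built in code; nothing is read from disk except what the
# tests themselves write to tempdirs

straight_fiber <- function(from = c(0, 0, 0), to = c(0, 0, 10), n = 11,
                           id = 1L, pathway = "test", hemisphere = "right") {
  s <- seq(0, 1, length.out = n)
  as_fiber_atlas(tibble::tibble(
    fiber_id = id, pathway = pathway, hemisphere = hemisphere,
    x = from[1] + s * (to[1] - from[1]),
    y = from[2] + s * (to[2] - from[2]),
    z = from[3] + s * (to[3] - from[3])))
}

single_source <- function(current_ma = -1, pos = c(0, 0, 0), sigma = 0.1) {
  point_source_field(
    tibble::tibble(x = pos[1], y = pos[2], z = pos[3],
                   current_ma = current_ma), sigma)
}

bipolar_field <- function(i_ma = 2, sep_mm = 2, sigma = 0.1,
                          flip = FALSE) {
  s <- if (flip) -1 else 1
  point_source_field(
    tibble::tibble(x = c(0, 0), y = c(0, 0), z = c(0, sep_mm),
                   current_ma = s * c(i_ma, -i_ma)), sigma)
}

# constant-field grid over a cube [-L, L]^3
constant_grid <- function(e = c(100, 0, 0), L = 10, n = 5) {
  arr <- array(0, dim = c(n, n, n, 3))
  for (k in 1:3) arr[, , , k] <- e[k]
  step <- 2 * L / (n - 1)
  aff <- rbind(cbind(diag(step, 3), c(-L, -L, -L)), c(0, 0, 0, 1))
  grid_field(arr, aff)
}

# perpendicular passing axon fixture: straight fibre along y at distance
# `dist` below a source at the origin; 12 mm keeps terminal AP detection
# within the post-pulse window even for the slowest (1 um) fibres
passing_axon <- function(dist = 1, len = 12, n = 61) {
  straight_fiber(from = c(0, -len / 2, -dist), to = c(0, len / 2, -dist),
                 n = n)
}

threshold_for <- function(diameter_um, pw_us = 60, dist = 1, sign = -1,
                          tol = 0.01) {
  fib <- passing_axon(dist = dist)
  spec <- axon_spec(diameter_um)
  geom <- build_axon(fib, spec)
  fld <- single_source(sign * 1)
  wf <- pulse_waveform(pw_us)
  drv <- extracellular_drive(geom, fld, wf)
  find_threshold(geom, drv, tol = tol)
}
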