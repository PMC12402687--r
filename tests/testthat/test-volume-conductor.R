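test_that("point-source potential and field match the closed forms", {
  fld <- single_source(current_ma = 1, sigma = 0.1)
  p <- c(1, 0, 0)  # r = 1 mm
  got <- field_at(fld, p)
  expect_equal(got$potential_v, 1e-3 / (4 * pi * 0.1 * 1e-3),
               tolerance = 1e-9)
  expect_equal(sqrt(got$ex^2 + got$ey^2 + got$ez^2),
               1e-3 / (4 * pi * 0.1 * 1e-6), tolerance = 1e-9)

  # balanced dipole: potential vanishes on the equidistant plane
  dip <- bipolar_field(i_ma = 1, sep_mm = 2)
  eq <- field_at(dip, c(3, 4, 1))
  expect_equal(eq$potential_v, 0, tolerance = 1e-15)

  # linearity: doubling all currents doubles V and E everywhere
  fld2 <- single_source(current_ma = 2, sigma = 0.1)
  set.seed(3)
  pts <- matrix(runif(30, 3, 9), ncol = 3)
  expect_equal(field_at(fld2, pts)$potential_v,
               2 * field_at(fld, pts)$potential_v, tolerance = 1e-12)
})

test_that("E is minus the gradient of V and superposition holds", {
  set.seed(11)
  src <- tibble::tibble(x = c(0, 1.5), y = c(0, 0), z = c(0, 2),
                        current_ma = c(2, -2))
  fld <- point_source_field(src, 0.1)
  pts <- matrix(runif(300, 2.5, 8), ncol = 3)
  h <- 1e-3  # 1 um central difference
  for (a in 1:3) {
    dp <- matrix(0, 1, 3); dp[a] <- h
    vp <- field_at(fld, pts + dp[rep(1, nrow(pts)), ])$potential_v
    vm <- field_at(fld, pts - dp[rep(1, nrow(pts)), ])$potential_v
    grad <- 1e3 * (vp - vm) / (2 * h)  # V/mm -> V/m
    e <- field_at(fld, pts)[[c("ex", "ey", "ez")[a]]]
    expect_true(all(abs(e + grad) <= 1e-4 * pmax(abs(e), 1)))
  }

  f1 <- single_source(2, c(0, 0, 0))
  f2 <- single_source(-2, c(1.5, 0, 2))
  both <- field_at(fld, pts)
  sep <- field_at(f1, pts)
  sep[] <- lapply(names(sep), function(nm) sep[[nm]] + field_at(f2, pts)[[nm]])
  for (nm in names(both)) {
    expect_equal(both[[nm]], sep[[nm]], tolerance = 1e-12)
  }
})

test_that("polarity inversion flips E exactly and preserves its magnitude", {
  fld <- bipolar_field(i_ma = 2)
  flp <- bipolar_field(i_ma = 2, flip = TRUE)
  pts <- matrix(runif(150, 2, 9), ncol = 3)
  a <- field_at(fld, pts); b <- field_at(flp, pts)
  expect_equal(b$ex, -a$ex, tolerance = 1e-15)
  expect_equal(b$potential_v, -a$potential_v, tolerance = 1e-15)
  expect_equal(sqrt(b$ex^2 + b$ey^2 + b$ez^2),
               sqrt(a$ex^2 + a$ey^2 + a$ez^2), tolerance = 1e-15)
})

test_that("singularity guard and parameter validation fire", {
  fld <- single_source(1)
  expect_error(field_at(fld, c(0.01, 0, 0)), "singular")
  expect_error(point_source_field(
    tibble::tibble(x = 0, y = 0, z = 0, current_ma = 1), sigma = 0), "sigma")
})

test_that("voltage-to-current conversion follows the isolated-sphere model", {
  contacts <- tibble::tibble(id = 0:3, x = 0, y = 0, z = c(0, 2, 4, 6))
  p <- stim_protocol(contacts, "voltage", amplitude = 1, pulse_width_us = 60,
                     frequency_hz = 130, polarity = "1+2-")
  pc <- voltage_to_current(p, sigma = 0.1, contact_radius = 0.635)
  expect_equal(pc$amplitude, 4 * pi * 0.1 * 0.635 * 1e-3 * 1 * 1e3,
               tolerance = 1e-12)  # 0.798 mA
  expect_equal(round(pc$amplitude, 3), 0.798)

  src <- protocol_sources(stim_protocol(contacts, "voltage", 2, 60, 130,
                                        polarity = "1+2-"))
  expect_equal(nrow(src), 2)
  expect_gt(src$current_ma[1], 0)   # contact 1 anodic
  expect_lt(src$current_ma[2], 0)   # contact 2 cathodic
  expect_equal(sum(src$current_ma), 0, tolerance = 1e-15)

  z <- protocol_sources(stim_protocol(contacts, "voltage", 0, 60, 130,
                                      polarity = "1+2-"))
  expect_true(all(z$current_ma == 0))

  expect_error(stim_protocol(contacts, "voltage", 1, 60, 130,
                             polarity = "abc"), "polarity")
})

test_that("protocol JSON round-trips", {
  contacts <- tibble::tibble(id = 0:3, x = 1, y = -2, z = c(0, 2, 4, 6))
  p <- stim_protocol(contacts, "voltage", 2.5, 70, 125, polarity = "2+3-")
  path <- file.path(withr::local_tempdir(), "proto.json")
  write_protocol(p, path)
  q <- read_protocol(path)
  expect_equal(q$amplitude, 2.5)
  expect_equal(q$pulse_width_us, 70)
  expect_equal(q$roles$role, p$roles$role)
  expect_equal(q$contacts$z, contacts$z)
})

test_that("grid fields interpolate exactly where trilinear must be exact", {
  g <- constant_grid(e = c(100, 0, 0))
  pts <- matrix(runif(60, -9, 9), ncol = 3)
  got <- field_at(g, pts)
  expect_true(all(abs(got$ex - 100) < 1e-12 & got$ey == 0 & got$ez == 0))

  # affine-linear field is reproduced exactly at arbitrary interior points
  n <- 6; L <- 10
  step <- 2 * L / (n - 1)
  coords <- seq(-L, L, length.out = n)
  lin <- function(x, y, z) cbind(2 * x - y, 3 * z + 1, x + y + z)
  arr <- array(0, dim = c(n, n, n, 3))
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    arr[i, j, k, ] <- lin(coords[i], coords[j], coords[k])
  }
  aff <- rbind(cbind(diag(step, 3), c(-L, -L, -L)), c(0, 0, 0, 1))
  gl <- grid_field(arr, aff)
  q <- matrix(runif(45, -8, 8), ncol = 3)
  got <- field_at(gl, q)
  truth <- lin(q[, 1], q[, 2], q[, 3])
  expect_equal(got$ex, truth[, 1], tolerance = 1e-12)
  expect_equal(got$ey, truth[, 2], tolerance = 1e-12)
  expect_equal(got$ez, truth[, 3], tolerance = 1e-12)

  expect_error(field_at(g, c(50, 0, 0)), "outside")
})

test_that("a sampled point-source grid agrees with the analytic field", {
  set.seed(5)
  sigma <- 0.1
  ana <- single_source(-2, c(0, 0, 0), sigma)
  # 0.2 mm lattice over [2, 6]^3, comfortably away from the source
  n <- 21
  coords <- seq(2, 6, length.out = n)
  arr <- array(0, dim = c(n, n, n, 3))
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    e <- field_at(ana, c(coords[i], coords[j], coords[k]))
    arr[i, j, k, ] <- c(e$ex, e$ey, e$ez)
  }
  aff <- rbind(cbind(diag(0.2, 3), c(2, 2, 2)), c(0, 0, 0, 1))
  g <- grid_field(arr, aff)
  q <- matrix(runif(150, 2.3, 5.7), ncol = 3)
  got <- field_at(g, q)
  ref <- field_at(ana, q)
  rel <- sqrt((got$ex - ref$ex)^2 + (got$ey - ref$ey)^2 +
                (got$ez - ref$ez)^2) /
    sqrt(ref$ex^2 + ref$ey^2 + ref$ez^2)
  expect_true(all(rel < 0.02))
})

test_that("field grids survive a NIfTI round-trip", {
  g <- constant_grid(e = c(7, -3, 2), L = 5, n = 4)
  path <- file.path(withr::local_tempdir(), "grid.nii.gz")
  write_field_grid(g, path)
  back <- read_field_grid(path)
  got <- field_at(back, c(1.3, -2.1, 0.4))
  expect_equal(c(got$ex, got$ey, got$ez), c(7, -3, 2), tolerance = 1e-5)
})
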