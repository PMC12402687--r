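test_that("node placement follows the internodal-length rule", {
  fib <- straight_fiber(c(0, 0, 0), c(20, 0, 0), n = 21)
  expect_equal(build_axon(fib, axon_spec(2))$n_nodes, 101)  # L = 0.2 mm
  expect_equal(build_axon(fib, axon_spec(4))$n_nodes, 51)   # L = 0.4 mm
  g <- build_axon(fib, axon_spec(2))
  expect_equal(diff(g$nodes$arc_mm), rep(0.2, 100), tolerance = 1e-6)
  # one node sits at mid-arc
  expect_true(any(abs(g$nodes$arc_mm - 10) < 1e-9))

  short <- straight_fiber(c(0, 0, 0), c(0.3, 0, 0), n = 3)
  expect_error(build_axon(short, axon_spec(2)), class = "axon_geometry_error")
})

test_that("the extracellular drive is linear and symmetry-faithful", {
  fib <- passing_axon(dist = 1)
  geom <- build_axon(fib, axon_spec(3))
  wf <- pulse_waveform(60)

  z <- extracellular_drive(geom, single_source(0), wf)
  expect_true(all(z$ve_mv == 0))
  expect_true(all(z$ve_at(0.12) == 0))

  d1 <- extracellular_drive(geom, single_source(-1), wf)
  d2 <- extracellular_drive(geom, single_source(-2), wf)
  expect_equal(d2$ve_mv, 2 * d1$ve_mv, tolerance = 1e-12)
  # waveform gating: zero before onset and after offset, full inside
  expect_true(all(d1$ve_at(0.05) == 0))
  expect_equal(d1$ve_at(0.12), d1$ve_mv)
  expect_true(all(d1$ve_at(0.2) == 0))

  # symmetric bipolar pair straddling the midpoint: antisymmetric profile
  straddle <- point_source_field(
    tibble::tibble(x = 0, y = c(-2, 2), z = 0, current_ma = c(1, -1)), 0.1)
  fib0 <- straight_fiber(c(0, -15, -1), c(0, 15, -1), n = 31)
  g0 <- build_axon(fib0, axon_spec(3))
  ds <- extracellular_drive(g0, straddle, wf)
  expect_equal(ds$ve_mv, -rev(ds$ve_mv), tolerance = 1e-9)
})

test_that("the membrane rests quietly and activates only above threshold", {
  fib <- passing_axon(dist = 1)
  spec <- axon_spec(3)
  geom <- build_axon(fib, spec)
  wf10 <- pulse_waveform(60, sim_window_ms = 10.1)
  rest <- simulate_axon(geom, extracellular_drive(geom, single_source(0), wf10))
  expect_false(rest$activated)
  expect_lt(rest$max_deviation_mv, 1)

  wf <- pulse_waveform(60)
  drv <- extracellular_drive(geom, single_source(-1), wf)
  thr <- find_threshold(geom, drv, tol = 0.01)
  up <- drv; up$ve_mv <- drv$ve_mv * 5 * thr
  dn <- drv; dn$ve_mv <- drv$ve_mv * 0.5 * thr
  expect_true(simulate_axon(geom, up)$activated)
  expect_false(simulate_axon(geom, dn)$activated)
  # the bisection brackets the transition at its stated tolerance
  at <- drv; at$ve_mv <- drv$ve_mv * thr * 1.011
  bt <- drv; bt$ve_mv <- drv$ve_mv * thr / 1.011
  expect_true(simulate_axon(geom, at)$activated)
  expect_false(simulate_axon(geom, bt)$activated)
})

test_that("action potentials start near the activating-function maximum", {
  fib <- passing_axon(dist = 1)
  spec <- axon_spec(3)
  geom <- build_axon(fib, spec)
  fld <- single_source(-1)
  wf <- pulse_waveform(60)
  drv <- extracellular_drive(geom, fld, wf)
  thr <- find_threshold(geom, drv, tol = 0.01)
  just <- drv; just$ve_mv <- drv$ve_mv * 1.05 * thr
  resp <- simulate_axon(geom, just)
  expect_true(resp$activated)

  h <- spec$internode_mm
  f <- activating_function(tibble::tibble(
    arc_mm = geom$nodes$arc_mm,
    potential_v = drv$ve_mv / 1000))
  expect_lte(abs(resp$initiation_node - which.max(f)), 2)
})

test_that("pPAM certainty is the activated fraction over the diameter grid", {
  fib <- passing_axon(dist = 1.5)
  wf <- pulse_waveform(60)
  res <- ppam(fib, single_source(-1.2), wf)
  expect_equal(res$n_samples, 10)
  expect_equal(res$diameters[[1]], seq(1, 4, length.out = 10))
  expect_equal(res$p_a, res$n_activated / res$n_samples)
  expect_equal(res$p_a * 10, round(res$p_a * 10))  # multiple of 1/N

  z <- ppam(fib, single_source(0), wf)
  expect_equal(z$p_a, 0)

  # random sampling mode is reproducible under an explicit seed
  r1 <- ppam(fib, single_source(-1.2), wf, sampling = "random", seed = 9)
  r2 <- ppam(fib, single_source(-1.2), wf, sampling = "random", seed = 9)
  expect_equal(r1$diameters, r2$diameters)
  expect_equal(r1$activations, r2$activations)
  expect_error(ppam(fib, single_source(-1), wf, sampling = "random"), "seed")

  # a fibre too short for any cable is reported, not simulated
  stub <- straight_fiber(c(5, 0, 0), c(5.15, 0, 0), n = 3)
  s <- ppam(stub, single_source(-1), wf)
  expect_equal(s$n_samples, 0)
  expect_true(is.na(s$p_a))
})

test_that("the flagged-fibre rule reproduces its Euclidean definition", {
  mk <- function(id, dist, flagged) {
    f <- straight_fiber(c(dist, -5, 0), c(dist, 5, 0), id = id)
    f$flagged <- flagged
    f
  }
  atlas <- as_fiber_atlas(dplyr::bind_rows(
    mk(1L, 4, FALSE),   # activated, most remote at 4 mm
    mk(2L, 2, FALSE),   # activated
    mk(3L, 3, TRUE),    # flagged, closer than 4 -> activated
    mk(4L, 5, TRUE)))   # flagged, farther -> not
  contacts <- matrix(c(0, 0, 0), ncol = 3)
  v <- flagged_fiber_rule(atlas, activated_ids = c(1L, 2L), contacts)
  expect_equal(v$fiber_id, c(3L, 4L))
  expect_equal(v$activated, c(TRUE, FALSE))
  expect_equal(v$distance_mm, c(3, 5), tolerance = 1e-12)

  none <- flagged_fiber_rule(atlas, activated_ids = integer(0), contacts)
  expect_false(any(none$activated))
  expect_error(flagged_fiber_rule(atlas, c(1L), matrix(numeric(0), ncol = 3)),
               "active contact")
})

test_that("ppam_atlas integrates simulation and the flagged rule", {
  atlas <- dplyr::bind_rows(
    straight_fiber(c(1.2, -10, 0), c(1.2, 10, 0), id = 1L),
    straight_fiber(c(8, -10, 0), c(8, 10, 0), id = 2L),
    {
      f <- straight_fiber(c(0.1, -10, 0), c(0.1, 10, 0), id = 3L)
      f$flagged <- TRUE
      f
    })
  atlas <- as_fiber_atlas(atlas)
  wf <- pulse_waveform(60)
  res <- ppam_atlas(atlas, single_source(-3), wf,
                    active_contacts = matrix(c(0, 0, 0), ncol = 3))
  expect_equal(nrow(res), 3)
  expect_true(res$flag_rule_applied[res$fiber_id == 3])
  near <- res$p_a[res$fiber_id == 1]
  far <- res$p_a[res$fiber_id == 2]
  expect_gte(near, far)  # closer fibre at least as recruited
  # the flagged fibre lies nearer the contact than fibre 1, so it inherits
  # activation whenever fibre 1 is activated
  if (near >= 0.5) expect_equal(res$p_a[res$fiber_id == 3], 1)
})
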