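#' Myelinated axon model specification
#'
#' Morphology and biophysics of the cable model: active nodes of Ranvier
#' with Frankenhaeuser-Huxley kinetics joined by perfectly insulating
#' internodes (the classic McNeal formulation).  Morphology follows the
#' standard scaling rules for a fibre of outer diameter D (um): internodal
#' length 100 D, axial (axoplasmic) diameter 0.7 D, node length 2.5 um.
#'
#' @param diameter_um fibre outer diameter, operating range 1-4 um.
#' @param internode_mm internodal spacing; default `0.1 * diameter_um` mm.
#' @param node_length_um nodal gap length, default 2.5.
#' @param axon_diameter_ratio axial-to-outer diameter ratio, default 0.7.
#' @param cm_uf_cm2 nodal membrane capacitance, default 2 uF/cm^2.
#' @param rho_axial_ohm_cm axoplasmic resistivity, default 110 Ohm cm.
#' @param temperature_c simulation temperature, default 37; nodal rate
#'   constants are Q10-scaled from their 20 C reference values.
#' @param dt_ms solver time step, default 0.005 ms (5 us, Crank-Nicolson).
#' @param detect_mv absolute membrane potential whose crossing at a
#'   terminal node counts as a propagated action potential, default 0 mV
#'   (rest is near -70 mV).
#' @param vrest_mv resting potential, default -70.
#' @return an `axon_spec` list.
#' @export
axon_spec <- function(diameter_um, internode_mm = NULL, node_length_um = 2.5,
                      axon_diameter_ratio = 0.7, cm_uf_cm2 = 2,
                      rho_axial_ohm_cm = 110, temperature_c = 37,
                      dt_ms = 0.005, detect_mv = 0, vrest_mv = -70) {
  if (diameter_um <= 0) abort("fibre diameter must be > 0 um")
  internode_mm <- internode_mm %||% (0.1 * diameter_um)
  vals <- c(internode_mm, node_length_um, axon_diameter_ratio, cm_uf_cm2,
            rho_axial_ohm_cm, dt_ms)
  if (any(vals <= 0)) abort("axon model parameters must be positive")
  structure(list(diameter_um = diameter_um, internode_mm = internode_mm,
                 node_length_um = node_length_um,
                 axon_diameter_ratio = axon_diameter_ratio,
                 cm_uf_cm2 = cm_uf_cm2, rho_axial_ohm_cm = rho_axial_ohm_cm,
                 temperature_c = temperature_c, dt_ms = dt_ms,
                 detect_mv = detect_mv, vrest_mv = vrest_mv),
            class = "axon_spec")
}

#' Place nodes of Ranvier along a fibre trajectory
#'
#' Nodes are spaced at the internodal length along the fibre's arc length
#' and centred so that one node sits at mid-arc; the ends are sealed.
#' Fibres shorter than two internodal lengths cannot carry a meaningful
#' cable and raise a geometry error (callers exclude and report them).
#'
#' @param fiber a single fibre: `fiber_atlas` rows of one `fiber_id`.
#' @param spec an [axon_spec()].
#' @return an `axon_geometry` list with the node positions (tibble
#'   `x`, `y`, `z`, `arc_mm`), `n_nodes`, `fiber_id` and the spec.
#' @export
build_axon <- function(fiber, spec) {
  ids <- unique(fiber$fiber_id)
  if (length(ids) != 1) abort("build_axon expects a single fibre")
  pts <- as.matrix(fiber[, c("x", "y", "z")])
  s <- arc_lengths(pts)
  total <- s[length(s)]
  L <- spec$internode_mm
  if (total < 2 * L) {
    abort(sprintf("fiber %s is too short for the cable (%.3f mm < 2 x %.3f mm)",
                  ids, total, L), class = "axon_geometry_error")
  }
  mid <- total / 2
  arcs <- mid + seq(-floor(mid / L + 1e-9), floor((total - mid) / L + 1e-9)) * L
  arcs <- pmin(pmax(arcs, 0), total)
  nodes <- tibble::tibble(
    x = approx(s, pts[, 1], xout = arcs)$y,
    y = approx(s, pts[, 2], xout = arcs)$y,
    z = approx(s, pts[, 3], xout = arcs)$y,
    arc_mm = arcs)
  structure(list(fiber_id = ids, nodes = nodes, n_nodes = nrow(nodes),
                 spec = spec),
            class = "axon_geometry")
}

#' Rectangular stimulus waveform
#'
#' Single monophasic rectangular pulse under the quasi-static separation:
#' the spatial potential distribution is scaled by this waveform in time.
#'
#' @param pulse_width_us pulse width in microseconds.
#' @param onset_ms pulse onset, default 0.1 ms.
#' @param sim_window_ms total simulated time; at least onset + pulse width
#'   + 3 ms (post-pulse window for propagation), which is the default.
#' @param amplitude_scale dimensionless multiplier on the protocol field.
#' @return a `pulse_waveform` list.
#' @export
pulse_waveform <- function(pulse_width_us, onset_ms = 0.1,
                           sim_window_ms = NULL, amplitude_scale = 1) {
  if (pulse_width_us <= 0) abort("pulse_width_us must be > 0")
  pw_ms <- pulse_width_us / 1000
  min_win <- onset_ms + pw_ms + 3
  sim_window_ms <- sim_window_ms %||% min_win
  if (sim_window_ms < min_win) {
    abort("sim_window_ms must cover onset + pulse width + 3 ms")
  }
  structure(list(pulse_width_us = pulse_width_us, onset_ms = onset_ms,
                 sim_window_ms = sim_window_ms,
                 amplitude_scale = amplitude_scale),
            class = "pulse_waveform")
}

#' Extracellular drive at the nodes of an axon
#'
#' Samples the field model's potential at the node positions and attaches
#' the pulse waveform; under the quasi-static approximation the nodal
#' extracellular potential is `Ve(i, t) = V(x_i) * w(t)`.
#'
#' @param geometry an [build_axon()] result.
#' @param field a field model.
#' @param waveform a [pulse_waveform()].
#' @return an `axon_drive` list with `ve_mv` (spatial profile at the nodes,
#'   mV), the waveform, and an evaluator `ve_at(t_ms)`.
#' @export
extracellular_drive <- function(geometry, field, waveform) {
  fs <- field_at(field, geometry$nodes)
  if (any(!is.finite(fs$potential_v))) {
    abort("field model returned no potential at one or more nodes")
  }
  ve <- 1000 * fs$potential_v * waveform$amplitude_scale  # mV
  drv <- list(ve_mv = ve, waveform = waveform, n_nodes = geometry$n_nodes)
  drv$ve_at <- function(t_ms) {
    on <- t_ms >= waveform$onset_ms &
      t_ms < waveform$onset_ms + waveform$pulse_width_us / 1000
    ve * as.numeric(on)
  }
  structure(drv, class = "axon_drive")
}

axon_membrane_geometry <- function(spec) {
  d_cm <- spec$axon_diameter_ratio * spec$diameter_um * 1e-4
  l_cm <- spec$node_length_um * 1e-4
  L_cm <- spec$internode_mm / 10
  list(area_cm2 = pi * d_cm * l_cm,
       ga_ms = 1000 * (pi * d_cm^2 / 4) / (spec$rho_axial_ohm_cm * L_cm))
}

#' Simulate one axon's response to a stimulus
#'
#' Solves the McNeal cable system (active FH nodes, insulating internodes)
#' by implicit time stepping (Crank-Nicolson on the axial coupling,
#' linearised-implicit ionic term).  The axon counts as activated when the
#' membrane potential crosses `detect_mv` (absolute, default 0 mV) at
#' either terminal node within the simulation window, i.e. when an action
#' potential has propagated to a fibre end.
#'
#' @param geometry an [build_axon()] result.
#' @param drive an [extracellular_drive()] result for the same geometry.
#' @param spec optional [axon_spec()] override; defaults to the geometry's.
#' @return an `axon_response` list: `activated`, `peak_vm_mv`,
#'   `detection_node`, `t_detect_ms`.
#' @export
simulate_axon <- function(geometry, drive, spec = NULL) {
  spec <- spec %||% geometry$spec
  if (drive$n_nodes != geometry$n_nodes) {
    abort("drive and geometry disagree on the node count")
  }
  g <- axon_membrane_geometry(spec)
  wf <- drive$waveform
  # divergence guard: beyond both the physiological envelope and what the
  # drive could passively impose (near-source nodes see volt-scale Ve)
  blow <- max(500, 1.5 * max(abs(drive$ve_mv)) + 100)
  res <- .fh_cable_sim(
    drive$ve_mv, spec$dt_ms, wf$sim_window_ms, wf$onset_ms,
    wf$onset_ms + wf$pulse_width_us / 1000,
    g$area_cm2, spec$cm_uf_cm2, g$ga_ms, spec$temperature_c,
    spec$vrest_mv, spec$detect_mv, blow)
  if (isTRUE(res$blowup)) {
    abort(sprintf(
      "cable solver diverged (|Vm| > 500 mV) for fiber %s: n_nodes=%d dt=%g ms, max drive %g mV",
      geometry$fiber_id, geometry$n_nodes, spec$dt_ms, max(abs(drive$ve_mv))),
      class = "axon_solver_error")
  }
  structure(list(activated = res$activated, peak_vm_mv = res$peak_vm_mv,
                 detection_node = res$detect_node,
                 initiation_node = res$init_node,
                 t_detect_ms = res$t_detect_ms,
                 max_deviation_mv = res$max_deviation_mv),
            class = "axon_response")
}

simulate_at_scale <- function(geometry, drive, scale, spec = NULL) {
  d2 <- drive
  d2$ve_mv <- drive$ve_mv * scale
  simulate_axon(geometry, d2, spec)
}

#' Activation threshold by bisection
#'
#' Scales the stimulus amplitude geometrically upward from the bottom of
#' the bracket until the axon activates, then bisects to the requested
#' relative tolerance.  The upward sweep (rather than probing the bracket
#' top) is deliberate: at extreme amplitudes conduction can fail through
#' hyperpolarising virtual anodes or depolarisation block, so activation
#' is not globally monotone in amplitude.
#'
#' @param geometry,drive as in [simulate_axon()]; the drive is taken at
#'   unit amplitude scale.
#' @param tol relative tolerance on the threshold, default 0.01.
#' @param bracket amplitude-scale search range, default `c(1e-3, 50)`.
#' @param base_amplitude_ma amplitude corresponding to scale 1; the return
#'   value is `scale * base_amplitude_ma` (mA).
#' @return threshold amplitude in mA (or amplitude scale when
#'   `base_amplitude_ma = 1`).
#' @export
find_threshold <- function(geometry, drive, tol = 0.01,
                           bracket = c(1e-3, 50), base_amplitude_ma = 1) {
  lo <- bracket[1]; hi <- NA_real_
  a <- lo
  while (a <= bracket[2]) {
    if (simulate_at_scale(geometry, drive, a)$activated) { hi <- a; break }
    lo <- a
    a <- a * 2
  }
  if (is.na(hi)) {
    abort(sprintf("no activation within amplitude bracket [%g, %g]",
                  bracket[1], bracket[2]),
          class = "axon_threshold_error")
  }
  while (hi / lo > 1 + tol) {
    mid <- sqrt(lo * hi)
    if (simulate_at_scale(geometry, drive, mid)$activated) hi <- mid else lo <- mid
  }
  hi * base_amplitude_ma
}

#' Probabilistic pathway activation for one fibre
#'
#' Repeats the cable simulation over fibre diameters sampled from
#' `[d_min, d_max]` (deterministic equispaced grid by default; seeded
#' uniform draws with `sampling = "random"`) and reports the activation
#' certainty `p(A) = N_activated / N_samples`.
#'
#' @param fiber a single fibre (rows of one `fiber_id`).
#' @param field a field model for the stimulation.
#' @param waveform a [pulse_waveform()].
#' @param d_min,d_max diameter range in um, defaults 1 and 4.
#' @param n_samples number of diameter samples, default 10.
#' @param sampling `"grid"` (default) or `"random"`.
#' @param seed RNG seed for `sampling = "random"`.
#' @param ... further arguments to [axon_spec()].
#' @return one-row tibble of class `ppam_result`: `fiber_id`, `n_samples`,
#'   `n_activated`, `p_a`, plus list-columns `diameters` and `activations`.
#'   Diameters whose cable does not fit the fibre are dropped from the
#'   sample set; if none fits, the fibre is reported with `n_samples = 0`
#'   and `p_a = NA`.
#' @export
ppam <- function(fiber, field, waveform, d_min = 1, d_max = 4,
                 n_samples = 10, sampling = c("grid", "random"),
                 seed = NULL, ...) {
  sampling <- match.arg(sampling)
  if (n_samples < 1) abort("n_samples must be >= 1")
  if (d_min >= d_max) abort("need d_min < d_max")
  diams <- if (sampling == "grid") {
    seq(d_min, d_max, length.out = n_samples)
  } else {
    if (is.null(seed)) abort("random diameter sampling needs an explicit seed")
    with_seed(seed, sort(runif(n_samples, d_min, d_max)))
  }
  act <- rep(NA, length(diams))
  for (i in seq_along(diams)) {
    spec <- axon_spec(diams[i], ...)
    geom <- tryCatch(build_axon(fiber, spec),
                     axon_geometry_error = function(e) NULL)
    if (is.null(geom)) next
    drv <- extracellular_drive(geom, field, waveform)
    resp <- tryCatch(simulate_axon(geom, drv),
                     axon_solver_error = function(e) {
                       warn(conditionMessage(e))
                       NULL
                     })
    if (!is.null(resp)) act[i] <- resp$activated
  }
  ok <- !is.na(act)
  out <- tibble::tibble(
    fiber_id = fiber$fiber_id[1],
    n_samples = sum(ok),
    n_activated = sum(act[ok] == TRUE),
    p_a = if (sum(ok) > 0) sum(act[ok] == TRUE) / sum(ok) else NA_real_,
    diameters = list(diams[ok]),
    activations = list(as.logical(act[ok])))
  class(out) <- c("ppam_result", class(out))
  out
}

#' Probabilistic PAM over a whole atlas
#'
#' Runs [ppam()] for every non-flagged fibre of the atlas; flagged fibres
#' (intersecting the electrode) are not probed and are afterwards assigned
#' by [flagged_fiber_rule()].
#'
#' @param atlas a `fiber_atlas`.
#' @param field,waveform,... as in [ppam()].
#' @param prob_cutoff binarisation cutoff used for the activated set handed
#'   to the flagged-fibre rule, default 0.5.
#' @param active_contacts positions of the active contacts (n-by-3 matrix
#'   or data frame); when supplied, flagged fibres receive verdicts via
#'   the Euclidean flagged-fibre rule and appear in the result with
#'   `flag_rule_applied = TRUE`.
#' @return tibble of class `ppam_result`, one row per fibre.
#' @export
ppam_atlas <- function(atlas, field, waveform, prob_cutoff = 0.5,
                       active_contacts = NULL, ...) {
  info <- fiber_info(atlas)
  sims <- lapply(info$fiber_id[!info$flagged], function(id) {
    ppam(atlas[atlas$fiber_id == id, ], field, waveform, ...)
  })
  out <- dplyr::bind_rows(sims)
  out <- dplyr::left_join(out,
                          info[, c("fiber_id", "pathway", "flagged")],
                          by = "fiber_id")
  out$flag_rule_applied <- FALSE
  if (any(info$flagged) && !is.null(active_contacts)) {
    activated_ids <- out$fiber_id[!is.na(out$p_a) & out$p_a >= prob_cutoff]
    verdicts <- flagged_fiber_rule(atlas, activated_ids, active_contacts)
    flag_rows <- tibble::tibble(
      fiber_id = verdicts$fiber_id, n_samples = NA_integer_,
      n_activated = NA_integer_,
      p_a = as.numeric(verdicts$activated),
      diameters = list(numeric(0)), activations = list(logical(0)),
      pathway = info$pathway[match(verdicts$fiber_id, info$fiber_id)],
      flagged = TRUE, flag_rule_applied = TRUE)
    out <- dplyr::bind_rows(out, flag_rows)
  }
  out <- out[order(out$fiber_id), ]
  class(out) <- c("ppam_result", class(tibble::tibble()))
  out
}

#' Euclidean heuristic for fibres intersecting the electrode
#'
#' Fibres that intersect the electrode body are not simulated.  Instead,
#' with c the centre point between the active contacts and R the distance
#' from c to the most remote activated fibre (minimum over each fibre's
#' points), a flagged fibre is deemed activated iff its own minimum
#' distance to c is smaller than R.
#'
#' @param atlas a `fiber_atlas` containing both flagged and activated fibres.
#' @param activated_ids fiber_ids deemed activated by simulation.
#' @param active_contacts positions of the active contacts.
#' @return tibble `fiber_id`, `distance_mm`, `activated` for the flagged
#'   fibres.
#' @export
flagged_fiber_rule <- function(atlas, activated_ids, active_contacts) {
  ac <- as_points_matrix(active_contacts)
  if (nrow(ac) == 0) abort("flagged-fibre rule needs at least one active contact")
  centre <- colMeans(ac)
  min_dist <- function(id) {
    pts <- fiber_points_matrix(atlas, id)
    sqrt(min(rowSums(sweep(pts, 2, centre)^2)))
  }
  flagged_ids <- unique(atlas$fiber_id[atlas$flagged])
  if (length(flagged_ids) == 0) {
    return(tibble::tibble(fiber_id = integer(0), distance_mm = numeric(0),
                          activated = logical(0)))
  }
  d_flagged <- vapply(flagged_ids, min_dist, numeric(1))
  if (length(activated_ids) == 0) {
    return(tibble::tibble(fiber_id = flagged_ids, distance_mm = d_flagged,
                          activated = FALSE))
  }
  r_max <- max(vapply(activated_ids, min_dist, numeric(1)))
  tibble::tibble(fiber_id = flagged_ids, distance_mm = d_flagged,
                 activated = d_flagged < r_max)
}
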