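#' Synthetic fibre-atlas specification
#'
#' Describes a set of fibre bundles laid out around a stimulation lead:
#' each bundle has a template curve (straight, arc or helix), a number of
#' fibres, a radial offset range from the lead axis, an orientation, a
#' length and a translational jitter.  The default bundle set emulates the
#' canonical geometric scenarios of lead-adjacent white matter: a bundle
#' passing perpendicular to the lead, a short bundle terminating near a
#' contact (the polarity-sensitive case), a long bundle parallel to the
#' lead, and a small bundle crossing the lead body (flagged).  Fibres of a
#' bundle are exact translates of its template curve plus seeded Gaussian
#' jitter.
#'
#' @param bundles list of bundle descriptors (see Details); `NULL` for the
#'   default set.
#' @param seed integer seed; all geometry randomness derives from it.
#' @param bilateral also generate the mirrored left-hemisphere copy.
#' @param lead_tip,lead_axis reference lead geometry the offsets refer to
#'   (right hemisphere).
#' @param include_degenerate add a tiny "stub" bundle too short to carry
#'   any cable model (exercises the geometry-error path).
#'
#' @details A bundle descriptor is a list with fields `label`, `geometry`
#' (`"straight"`, `"arc"`, `"helix"`), `n_fibers`, `offset_mm` (radial
#' range `c(min, max)` from the lead axis), `z_range` (range along the
#' lead relative to the tip), `orientation` (template direction),
#' `length_mm`, `jitter_sd_mm`, and `terminate` (`TRUE` places the curve
#' start, rather than its midpoint, at the offset point so the fibre
#' terminates near the lead).
#' @return a `synthetic_atlas_spec` list.
#' @export
synthetic_atlas_spec <- function(bundles = NULL, seed = 42, bilateral = TRUE,
                                 lead_tip = c(12, -13, -9),
                                 lead_axis = c(0, 0, 1),
                                 include_degenerate = FALSE) {
  if (is.null(bundles)) {
    bundles <- list(
      list(label = "hyperdirect_passing", geometry = "straight",
           n_fibers = 40, offset_mm = c(1.2, 3.6), z_range = c(0.5, 5.5),
           orientation = c(0, 1, 0), length_mm = 30, jitter_sd_mm = 0.15,
           terminate = FALSE),
      list(label = "pallido_terminating", geometry = "arc",
           n_fibers = 24, offset_mm = c(0.9, 2.2), z_range = c(1.2, 2.8),
           orientation = c(-1, 0, 0), length_mm = 9, jitter_sd_mm = 0.15,
           terminate = TRUE),
      list(label = "cst_parallel", geometry = "straight",
           n_fibers = 20, offset_mm = c(2.0, 4.0), z_range = c(2.5, 3.5),
           orientation = c(0, 0, 1), length_mm = 30, jitter_sd_mm = 0.15,
           terminate = FALSE),
      list(label = "lead_crossing", geometry = "straight",
           n_fibers = 6, offset_mm = c(0, 0.3), z_range = c(2.0, 4.0),
           orientation = c(1, 0, 0), length_mm = 14, jitter_sd_mm = 0.1,
           terminate = FALSE))
  }
  if (include_degenerate) {
    bundles <- c(bundles, list(
      list(label = "stub_degenerate", geometry = "straight",
           n_fibers = 3, offset_mm = c(4, 5), z_range = c(0, 1),
           orientation = c(0, 1, 0), length_mm = 0.15, jitter_sd_mm = 0,
           terminate = FALSE)))
  }
  for (b in bundles) {
    if (b$n_fibers < 1) abort("each bundle needs n_fibers >= 1")
    if (b$jitter_sd_mm < 0) abort("jitter_sd_mm must be >= 0")
  }
  structure(list(bundles = bundles, seed = as.integer(seed),
                 bilateral = bilateral, lead_tip = lead_tip,
                 lead_axis = lead_axis / sqrt(sum(lead_axis^2))),
            class = "synthetic_atlas_spec")
}

# template curves, all starting at the origin; arc curls in the x-z plane
# of the local frame, helix winds around the local z axis
template_curve <- function(geometry, orientation, length_mm, terminate,
                           step_mm = 1) {
  n <- max(3, ceiling(length_mm / step_mm) + 1)
  s <- seq(0, length_mm, length.out = n)
  u <- orientation / sqrt(sum(orientation^2))
  helper <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  v <- helper - sum(helper * u) * u
  v <- v / sqrt(sum(v^2))
  pts <- switch(geometry,
    straight = outer(s, u),
    arc = {
      r <- 2 * length_mm / pi  # quarter-circle curvature scaled to length
      th <- s / r
      outer(r * sin(th), u) + outer(r * (1 - cos(th)), v)
    },
    helix = {
      r <- 2
      pitch <- 4
      k <- sqrt((2 * pi * r)^2 + pitch^2) / pitch
      th <- 2 * pi * s / (k * pitch)
      outer(r * sin(th), u) + outer(r * (1 - cos(th)), v) +
        outer(s / k, u * 0 + cross3(u, v))
    },
    abort(paste0("unknown bundle geometry: ", geometry)))
  if (!terminate) pts <- sweep(pts, 2, pts[ceiling(n / 2), ])
  pts
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Generate a synthetic fibre atlas
#'
#' Deterministic under the spec's seed: fibre offsets, azimuths and jitter
#' are drawn from a seeded substream, so repeated calls (and the files
#' they produce) are identical.
#'
#' @param spec a [synthetic_atlas_spec()].
#' @param electrode an electrode from [make_electrode()] used to flag
#'   fibres intersecting the lead body; `NULL` builds the default lead at
#'   the spec's reference geometry.
#' @return a `fiber_atlas`; bilateral atlases carry a `mirror_map`
#'   attribute (tibble `left_id`, `right_id`).
#' @export
make_synthetic_atlas <- function(spec = synthetic_atlas_spec(),
                                 electrode = NULL) {
  if (is.null(electrode)) {
    electrode <- make_electrode(tip = spec$lead_tip, axis = spec$lead_axis)
  }
  axis <- spec$lead_axis
  tip <- spec$lead_tip
  helper <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- helper - sum(helper * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(axis, e1)

  rows <- with_seed(substream(spec$seed, "atlas"), {
    next_id <- 1L
    out <- list()
    for (b in spec$bundles) {
      tpl <- template_curve(b$geometry, b$orientation, b$length_mm,
                            b$terminate)
      for (j in seq_len(b$n_fibers)) {
        r <- runif(1, b$offset_mm[1], b$offset_mm[2])
        phi <- runif(1, 0, 2 * pi)
        zc <- runif(1, b$z_range[1], b$z_range[2])
        jit <- if (b$jitter_sd_mm > 0) rnorm(3, 0, b$jitter_sd_mm) else c(0, 0, 0)
        centre <- tip + zc * axis + r * (cos(phi) * e1 + sin(phi) * e2) + jit
        pts <- sweep(tpl, 2, centre, "+")
        out[[length(out) + 1]] <- tibble::tibble(
          fiber_id = next_id, pathway = b$label, hemisphere = "right",
          x = pts[, 1], y = pts[, 2], z = pts[, 3])
        next_id <- next_id + 1L
      }
    }
    out
  })
  atlas <- dplyr::bind_rows(rows)
  atlas$flagged <- FALSE
  atlas <- as_fiber_atlas(atlas, space_tag = "synthetic-ras")
  atlas <- flag_fibers(atlas, electrode)
  if (spec$bilateral) {
    offset <- max(atlas$fiber_id)
    left <- mirror_fibers(atlas, id_offset = offset)
    both <- dplyr::bind_rows(atlas, left)
    both <- as_fiber_atlas(both, space_tag = "synthetic-ras")
    # left fibres keep their flags from the mirrored right construction
    attr(both, "mirror_map") <- tibble::tibble(
      left_id = sort(unique(left$fiber_id)),
      right_id = sort(unique(left$fiber_id)) - offset)
    attr(both, "mirror_offset") <- offset
    return(both)
  }
  atlas
}

#' Four-level omnidirectional stimulation lead
#'
#' Contact centres are spaced `contact_spacing` mm along the lead axis
#' starting at the tip; the lead body is a cylinder of radius 0.635 mm
#' used for fibre flagging.
#'
#' @param tip 3D tip position (mm), centre of the lowest contact.
#' @param axis unit lead direction.
#' @param contact_spacing centre-to-centre spacing, default 2 mm.
#' @param n_contacts default 4.
#' @param radius lead radius, default 0.635 mm.
#' @param shaft_length_mm extent of the cylinder used for intersection
#'   tests, default 40 mm from 1 mm below the tip.
#' @return an `electrode` list: `contacts` (tibble `id`, `x`, `y`, `z`),
#'   `tip`, `axis`, `radius`.
#' @export
make_electrode <- function(tip = c(12, -13, -9), axis = c(0, 0, 1),
                           contact_spacing = 2, n_contacts = 4,
                           radius = 0.635, shaft_length_mm = 40) {
  axis <- axis / sqrt(sum(axis^2))
  z <- contact_spacing * (seq_len(n_contacts) - 1)
  contacts <- tibble::tibble(
    id = seq_len(n_contacts) - 1L,
    x = tip[1] + z * axis[1], y = tip[2] + z * axis[2],
    z = tip[3] + z * axis[3])
  structure(list(contacts = contacts, tip = tip, axis = axis,
                 radius = radius, shaft_length_mm = shaft_length_mm),
            class = "electrode")
}

# minimum distance of points to the lead's shaft segment
dist_to_lead <- function(pts, electrode) {
  a <- electrode$tip - electrode$axis  # 1 mm below the tip
  u <- electrode$axis
  rel <- sweep(as.matrix(pts), 2, a)
  t <- pmin(pmax(rel %*% u, 0), electrode$shaft_length_mm)
  closest <- outer(as.numeric(t), u)
  sqrt(rowSums((rel - closest)^2))
}

#' Reconstruct a lead from a protocol's contact geometry
#'
#' Tip at the first contact, axis along the contact row; used to re-flag
#' fibres against the lead of a specific stimulation.
#'
#' @param protocol a [stim_protocol()].
#' @param radius lead radius, mm.
#' @return an `electrode`.
#' @export
electrode_from_protocol <- function(protocol, radius = 0.635) {
  ct <- protocol$contacts
  axis <- c(ct$x[nrow(ct)] - ct$x[1], ct$y[nrow(ct)] - ct$y[1],
            ct$z[nrow(ct)] - ct$z[1])
  make_electrode(tip = c(ct$x[1], ct$y[1], ct$z[1]), axis = axis,
                 radius = radius)
}

#' Flag fibres intersecting the electrode body
#'
#' @param atlas a `fiber_atlas`.
#' @param electrode an [make_electrode()] lead.
#' @return the atlas with `flagged = TRUE` for every fibre that comes
#'   within the lead radius of the shaft.
#' @export
flag_fibers <- function(atlas, electrode) {
  d <- dist_to_lead(atlas[, c("x", "y", "z")], electrode)
  hit <- tapply(d < electrode$radius, atlas$fiber_id, any)
  atlas$flagged <- as.logical(hit[as.character(atlas$fiber_id)])
  atlas
}

#' Synthetic cohort specification
#'
#' Conditions of the emulated clinical study: 15 patients with bilateral
#' bipolar stimulation (one stimulation per hemisphere), voltage-controlled
#' protocols in the clinically typical 1.5-5 V / 60-90 us / 90-160 Hz
#' range, and a continuous outcome (% motor improvement) driven by the
#' activated fraction of one designated pathway plus Gaussian noise.
#'
#' @param effect_pathway pathway whose recruitment drives the outcome.
#' @param n_patients default 15.
#' @param effect_size outcome % per unit activated fraction, default 40.
#' @param noise_sd outcome noise SD in %, default 5.
#' @param baseline outcome at zero recruitment, default 20 %.
#' @param electrode_jitter_sd_mm per-hemisphere lateral implantation
#'   variability, default 0.8 mm.
#' @param seed integer seed.
#' @return a `synthetic_cohort_spec` list.
#' @export
synthetic_cohort_spec <- function(effect_pathway = "hyperdirect_passing",
                                  n_patients = 15, effect_size = 40,
                                  noise_sd = 5, baseline = 20,
                                  electrode_jitter_sd_mm = 0.8, seed = 42) {
  if (n_patients < 2) abort("need n_patients >= 2")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  structure(list(effect_pathway = effect_pathway,
                 n_patients = as.integer(n_patients),
                 effect_size = effect_size, noise_sd = noise_sd,
                 baseline = baseline,
                 electrode_jitter_sd_mm = electrode_jitter_sd_mm,
                 seed = as.integer(seed)),
            class = "synthetic_cohort_spec")
}

#' Generate a synthetic stimulation cohort
#'
#' Per patient and hemisphere: a seeded per-hemisphere electrode
#' displacement (implantation variability), a bipolar protocol with a
#' random adjacent contact pair, polarity orientation, voltage, pulse
#' width and frequency; the patient outcome is
#' `baseline + effect_size * mean(activated fraction of the effect pathway
#' over both hemispheres) + N(0, noise_sd)`, where the generator's
#' reference activation is the binary thresholded field magnitude
#' (peak ||E|| >= 200 V/m).
#'
#' @param spec a [synthetic_cohort_spec()].
#' @param atlas a bilateral `fiber_atlas` from [make_synthetic_atlas()].
#' @param electrode the reference right-hemisphere lead.
#' @param sigma conductivity used by the reference field, S/m.
#' @return list with `cohort` (tibble: `stim_id`, `patient_id`,
#'   `hemisphere`, `outcome_percent`, protocol columns), `protocols`
#'   (named list of [stim_protocol()]), `electrodes` (named list of
#'   per-stimulation leads).
#' @export
make_cohort <- function(spec, atlas, electrode, sigma = 0.1) {
  info <- fiber_info(atlas)
  if (!spec$effect_pathway %in% info$pathway) {
    abort(paste0("effect_pathway '", spec$effect_pathway,
                 "' is not in the atlas"))
  }
  mirror_tip <- function(tip) c(-tip[1], tip[2], tip[3])
  rows <- list(); protocols <- list(); electrodes <- list()
  with_seed(substream(spec$seed, "cohort"), {
    for (p in seq_len(spec$n_patients)) {
      fracs <- c(right = NA_real_, left = NA_real_)
      for (hemi in c("right", "left")) {
        jit <- rnorm(2, 0, spec$electrode_jitter_sd_mm)
        tip <- electrode$tip + c(jit[1], jit[2], 0)
        if (hemi == "left") tip <- mirror_tip(tip)
        lead <- make_electrode(tip = tip, axis = electrode$axis,
                               radius = electrode$radius)
        pair_low <- sample(0:2, 1)
        anode_upper <- runif(1) < 0.5
        sig <- if (anode_upper) {
          sprintf("%d-%d+", pair_low, pair_low + 1)
        } else {
          sprintf("%d+%d-", pair_low, pair_low + 1)
        }
        volt <- round(runif(1, 1.5, 5), 1)
        pw <- sample(c(60, 70, 80, 90), 1)
        fr <- sample(c(90, 125, 130, 145, 160), 1)
        proto <- stim_protocol(lead$contacts, mode = "voltage",
                               amplitude = volt, pulse_width_us = pw,
                               frequency_hz = fr, polarity = sig)
        stim_id <- sprintf("P%02d_%s", p, hemi)
        protocols[[stim_id]] <- proto
        electrodes[[stim_id]] <- lead
        # reference recruitment: peak ||E|| >= 200 V/m on the effect
        # bundle, fibres intersecting this stimulation's lead handled by
        # the Euclidean flagged-fibre rule
        hemi_fibers <- atlas[atlas$pathway == spec$effect_pathway &
                               atlas$hemisphere == hemi, ]
        hemi_fibers <- flag_fibers(hemi_fibers, lead)
        field <- point_source_field(protocol_sources(proto, sigma), sigma)
        nf <- hemi_fibers[!hemi_fibers$flagged, ]
        fm <- fiber_metrics(nf, field, metric_config("magnitude", "peak"))
        driven <- proto$roles
        ac <- lead$contacts[match(driven$id, lead$contacts$id),
                            c("x", "y", "z")]
        fv <- flagged_fiber_rule(hemi_fibers, fm$fiber_id[fm$binary], ac)
        fracs[hemi] <- (sum(fm$binary) + sum(fv$activated)) /
          (nrow(fm) + nrow(fv))
        rows[[length(rows) + 1]] <- tibble::tibble(
          stim_id = stim_id, patient_id = p, hemisphere = hemi,
          polarity = sig, voltage_v = volt, pulse_width_us = pw,
          frequency_hz = fr, effect_fraction = fracs[hemi])
      }
      noise <- rnorm(1, 0, spec$noise_sd)
      outcome <- spec$baseline + spec$effect_size * mean(fracs) + noise
      n <- length(rows)
      rows[[n - 1]]$outcome_percent <- outcome
      rows[[n]]$outcome_percent <- outcome
    }
  })
  cohort <- dplyr::bind_rows(rows)
  list(cohort = cohort, protocols = protocols, electrodes = electrodes)
}
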