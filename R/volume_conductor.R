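#' Point-source volume conductor
#'
#' Analytic quasi-static field of point current sources in an infinite
#' homogeneous isotropic medium of conductivity `sigma`:
#' \deqn{V(x) = \sum_i I_i / (4 \pi \sigma \|x - x_i\|), \quad
#'       E(x) = \sum_i I_i (x - x_i) / (4 \pi \sigma \|x - x_i\|^3)}
#' with currents in mA, distances in mm, potentials in V and fields in V/m.
#' This deliberately simple conductor stands behind the same interface as
#' imported field grids, so the metric and axon layers are agnostic to how
#' the field was produced.
#'
#' @param sources tibble with columns `x`, `y`, `z` (mm) and `current_ma`
#'   (signed; negative = cathodic).
#' @param sigma conductivity in S/m, default 0.1.
#' @return an object of class `point_source_field`.
#' @export
point_source_field <- function(sources, sigma = 0.1) {
  if (!is.numeric(sigma) || sigma <= 0) abort("sigma must be > 0 (S/m)")
  need <- c("x", "y", "z", "current_ma")
  if (!all(need %in% names(sources))) {
    abort("sources need columns x, y, z, current_ma")
  }
  sources <- tibble::as_tibble(sources)[, need]
  if (!all(vapply(sources, function(c) all(is.finite(c)), TRUE))) {
    abort("source positions and currents must be finite")
  }
  structure(list(sources = sources, sigma = sigma),
            class = "point_source_field")
}

# mm distance below which a query is treated as sitting on the source
SINGULARITY_GUARD_MM <- 0.05

as_points_matrix <- function(points) {
  if (is.matrix(points)) {
    m <- points
  } else if (is.data.frame(points)) {
    m <- as.matrix(points[, c("x", "y", "z")])
  } else if (is.numeric(points) && length(points) == 3) {
    m <- matrix(points, ncol = 3)
  } else {
    abort("points must be a data frame with x,y,z, an n-by-3 matrix, or a 3-vector")
  }
  storage.mode(m) <- "double"
  m
}

#' Evaluate a field model at query points
#'
#' @param field a `point_source_field` or `grid_field`.
#' @param points data frame with `x`, `y`, `z` (mm), matrix, or 3-vector.
#' @return tibble with `potential_v`, `ex`, `ey`, `ez` (V/m) per point.
#' @export
field_at <- function(field, points) UseMethod("field_at")

#' @export
field_at.point_source_field <- function(field, points) {
  pts <- as_points_matrix(points)
  src <- field$sources
  n <- nrow(pts)
  pot <- numeric(n)
  e <- matrix(0, n, 3)
  for (k in seq_len(nrow(src))) {
    dxyz <- sweep(pts, 2, c(src$x[k], src$y[k], src$z[k]))
    r <- sqrt(rowSums(dxyz^2))
    if (any(r < SINGULARITY_GUARD_MM)) {
      abort(sprintf("query within %.2f mm of a source: potential is singular",
                    SINGULARITY_GUARD_MM))
    }
    # I[mA], r[mm]: V = I/(4 pi sigma r) volts; E = 1e3 * I/(4 pi sigma r^2) V/m
    pot <- pot + src$current_ma[k] / (4 * pi * field$sigma * r)
    e <- e + 1e3 * src$current_ma[k] * dxyz / (4 * pi * field$sigma * r^3)
  }
  tibble::tibble(potential_v = pot, ex = e[, 1], ey = e[, 2], ez = e[, 3])
}

#' @rdname field_at
#' @param sources,sigma as in [point_source_field()].
#' @export
potential_at <- function(sources, points, sigma = 0.1) {
  field_at(point_source_field(sources, sigma), points)$potential_v
}

#' @rdname field_at
#' @export
efield_at <- function(sources, points, sigma = 0.1) {
  out <- field_at(point_source_field(sources, sigma), points)
  out[, c("ex", "ey", "ez")]
}

#' Stimulation protocols
#'
#' A stimulation protocol holds the lead contact geometry and the electrical
#' settings of one stimulation: mode (`voltage` or `current`), set amplitude,
#' pulse width and frequency, and a polarity signature such as `"1+2-"`
#' (contact 1 anodic, contact 2 cathodic).  Bipolar settings are
#' charge-balanced: the driven anodes and cathodes share the same total
#' current with opposite signs.  Monopolar settings name only cathodes (or
#' only anodes) with the return at infinity.
#'
#' @param contacts tibble with columns `id` (integer), `x`, `y`, `z` (mm).
#' @param mode `"voltage"` or `"current"`.
#' @param amplitude set amplitude: V in voltage mode, mA in current mode.
#' @param pulse_width_us pulse width in microseconds (> 0).
#' @param frequency_hz stimulation frequency in Hz (> 0); recorded, unused
#'   by the single-pulse axon simulation.
#' @param polarity signature string, e.g. `"1+2-"` or `"2-"` (monopolar).
#' @return an object of class `stim_protocol`.
#' @export
stim_protocol <- function(contacts, mode = c("voltage", "current"),
                          amplitude, pulse_width_us = 60,
                          frequency_hz = 130, polarity) {
  mode <- match.arg(mode)
  contacts <- tibble::as_tibble(contacts)
  if (!all(c("id", "x", "y", "z") %in% names(contacts))) {
    abort("contacts need columns id, x, y, z")
  }
  if (pulse_width_us <= 0) abort("pulse_width_us must be > 0")
  if (frequency_hz <= 0) abort("frequency_hz must be > 0")
  roles <- parse_polarity(polarity)
  unknown <- setdiff(roles$id, contacts$id)
  if (length(unknown) > 0) {
    abort(paste0("polarity names contact(s) not on the lead: ",
                 paste(unknown, collapse = ", ")))
  }
  structure(list(contacts = contacts, mode = mode, amplitude = amplitude,
                 pulse_width_us = pulse_width_us, frequency_hz = frequency_hz,
                 polarity = polarity, roles = roles),
            class = "stim_protocol")
}

# "1+2-" -> tibble(id, role); multi-contact forms like "1+2-3-" supported
parse_polarity <- function(signature) {
  sig <- gsub("[[:space:]]", "", signature)
  m <- gregexpr("[0-9]+[+-]", sig)[[1]]
  toks <- regmatches(sig, gregexpr("[0-9]+[+-]", sig))[[1]]
  if (length(toks) == 0 || sum(attr(m, "match.length")) != nchar(sig)) {
    abort(paste0("cannot parse polarity signature: '", signature, "'"))
  }
  tibble::tibble(
    id = as.integer(sub("[+-]$", "", toks)),
    role = ifelse(grepl("\\+$", toks), "anode", "cathode"))
}

#' Convert a voltage-controlled protocol to current control
#'
#' Uses an isolated-sphere access-resistance model: a driven contact of
#' equivalent radius \eqn{r_c} in a medium of conductivity \eqn{\sigma}
#' passes \eqn{I = 4 \pi \sigma r_c V} at set voltage \eqn{V}.  The total
#' current is split equally among same-polarity contacts, so bipolar
#' settings stay charge-balanced.  This is a declared approximation, not a
#' model of any commercial pulse generator.
#'
#' @param protocol a voltage-mode [stim_protocol()].
#' @param sigma conductivity S/m.
#' @param contact_radius equivalent sphere radius in mm, default 0.635
#'   (cylindrical-contact equivalent).
#' @return a current-mode `stim_protocol` (amplitude in mA).
#' @export
voltage_to_current <- function(protocol, sigma = 0.1, contact_radius = 0.635) {
  if (protocol$mode != "voltage") abort("protocol is not voltage-controlled")
  if (contact_radius <= 0) abort("contact_radius must be > 0 (mm)")
  i_total <- 4 * pi * sigma * contact_radius * protocol$amplitude  # mA
  out <- protocol
  out$mode <- "current"
  out$amplitude <- i_total
  out
}

#' Signed point sources for a protocol
#'
#' Expands a protocol into per-contact point sources: cathodes share
#' `-amplitude`, anodes `+amplitude` (each side split equally).  Voltage-mode
#' protocols are converted with [voltage_to_current()] first.
#'
#' @inheritParams voltage_to_current
#' @return tibble with `x`, `y`, `z`, `current_ma`.
#' @export
protocol_sources <- function(protocol, sigma = 0.1, contact_radius = 0.635) {
  if (protocol$mode == "voltage") {
    protocol <- voltage_to_current(protocol, sigma, contact_radius)
  }
  roles <- protocol$roles
  n_an <- sum(roles$role == "anode")
  n_ca <- sum(roles$role == "cathode")
  cur <- ifelse(roles$role == "anode",
                if (n_an > 0) protocol$amplitude / n_an else 0,
                if (n_ca > 0) -protocol$amplitude / n_ca else 0)
  pos <- protocol$contacts[match(roles$id, protocol$contacts$id), ]
  tibble::tibble(x = pos$x, y = pos$y, z = pos$z, current_ma = cur)
}

#' @rdname stim_protocol
#' @param path JSON file with keys `contacts` (list of `{id, position_mm,
#'   role}`), `mode`, `amplitude`, `pulse_width_us`, `frequency_hz`.
#' @export
read_protocol <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  need <- c("contacts", "mode", "amplitude", "pulse_width_us", "frequency_hz")
  miss <- setdiff(need, names(j))
  if (length(miss) > 0) {
    abort(paste0("protocol JSON missing key(s): ", paste(miss, collapse = ", ")))
  }
  contacts <- purrr::map_dfr(j$contacts, function(ct) {
    tibble::tibble(id = ct$id, x = ct$position_mm[[1]],
                   y = ct$position_mm[[2]], z = ct$position_mm[[3]],
                   role = ct$role %||% "off")
  })
  driven <- contacts[contacts$role != "off", ]
  sig <- paste0(driven$id, ifelse(driven$role == "anode", "+", "-"),
                collapse = "")
  stim_protocol(contacts[, c("id", "x", "y", "z")], mode = j$mode,
                amplitude = j$amplitude, pulse_width_us = j$pulse_width_us,
                frequency_hz = j$frequency_hz, polarity = sig)
}

#' @rdname stim_protocol
#' @param protocol a `stim_protocol` to serialise.
#' @export
write_protocol <- function(protocol, path) {
  roles <- protocol$roles
  contacts <- purrr::pmap(protocol$contacts, function(id, x, y, z, ...) {
    role <- roles$role[match(id, roles$id)]
    list(id = id, position_mm = c(x, y, z),
         role = if (is.na(role)) "off" else role)
  })
  jsonlite::write_json(
    list(contacts = contacts, mode = protocol$mode,
         amplitude = protocol$amplitude,
         pulse_width_us = protocol$pulse_width_us,
         frequency_hz = protocol$frequency_hz,
         polarity = protocol$polarity),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Imported field grids
#'
#' Reads a 4-D NIfTI volume holding the three electric-field components
#' (Ex, Ey, Ez) in V/m on an RAS lattice, optionally with a companion
#' scalar-potential volume.  Queries are answered by trilinear
#' interpolation; points outside the lattice raise an out-of-domain error
#' (no extrapolation).
#'
#' @param path 4-D NIfTI file (last dimension = 3 components).
#' @param potential_path optional 3-D NIfTI with the potential in V.
#' @return an object of class `grid_field`.
#' @export
read_field_grid <- function(path, potential_path = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4 || dim(arr)[4] != 3) {
    abort("field grid must be 4-D NIfTI with 3 components")
  }
  if (any(dim(arr)[1:3] < 2)) abort("field grid needs >= 2 voxels per axis")
  aff <- structure(RNifti::xform(img), class = NULL)
  pot <- NULL
  if (!is.null(potential_path)) {
    pot <- as.array(RNifti::readNifti(potential_path))
    if (!all(dim(pot)[1:3] == dim(arr)[1:3])) {
      abort("potential grid dimensions do not match the field grid")
    }
  }
  grid_field(arr, aff, potential = pot)
}

#' @rdname read_field_grid
#' @param field_array X-by-Y-by-Z-by-3 array of field components (V/m).
#' @param affine 4x4 voxel-to-mm affine (0-based voxel indices).
#' @param potential optional X-by-Y-by-Z array of potentials (V).
#' @export
grid_field <- function(field_array, affine, potential = NULL) {
  if (abs(det(affine)) < 1e-12) abort("grid affine is not invertible")
  structure(list(field = field_array, affine = affine,
                 inv_affine = solve(affine), potential = potential,
                 dims = dim(field_array)[1:3]),
            class = "grid_field")
}

#' @export
field_at.grid_field <- function(field, points) {
  pts <- as_points_matrix(points)
  vox <- cbind(pts, 1) %*% t(field$inv_affine)  # 0-based voxel coordinates
  d <- field$dims
  out <- sapply(1:3, function(a) vox[, a])
  if (is.null(dim(out))) out <- matrix(out, ncol = 3)
  lo <- c(0, 0, 0); hi <- d - 1
  bad <- out[, 1] < lo[1] | out[, 1] > hi[1] | out[, 2] < lo[2] |
    out[, 2] > hi[2] | out[, 3] < lo[3] | out[, 3] > hi[3]
  if (any(bad)) {
    abort(sprintf("%d query point(s) outside the field grid domain", sum(bad)))
  }
  tri <- function(vol) trilinear(vol, out)
  res <- tibble::tibble(
    potential_v = if (is.null(field$potential)) NA_real_ else tri(field$potential),
    ex = tri(field$field[, , , 1]), ey = tri(field$field[, , , 2]),
    ez = tri(field$field[, , , 3]))
  res
}

# trilinear interpolation at 0-based voxel coordinates
trilinear <- function(vol, vox) {
  d <- dim(vol)
  i0 <- pmin(pmax(floor(vox[, 1]), 0), d[1] - 2)
  j0 <- pmin(pmax(floor(vox[, 2]), 0), d[2] - 2)
  k0 <- pmin(pmax(floor(vox[, 3]), 0), d[3] - 2)
  fx <- vox[, 1] - i0; fy <- vox[, 2] - j0; fz <- vox[, 3] - k0
  at <- function(di, dj, dk) vol[cbind(i0 + di + 1, j0 + dj + 1, k0 + dk + 1)]
  at(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(1, 0, 0) * fx * (1 - fy) * (1 - fz) +
    at(0, 1, 0) * (1 - fx) * fy * (1 - fz) +
    at(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
    at(1, 1, 0) * fx * fy * (1 - fz) +
    at(1, 0, 1) * fx * (1 - fy) * fz +
    at(0, 1, 1) * (1 - fx) * fy * fz +
    at(1, 1, 1) * fx * fy * fz
}

#' Sample a precomputed field grid
#' @param grid a `grid_field`.
#' @param points query points (data frame with x,y,z, matrix, or 3-vector).
#' @return tibble as in [field_at()].
#' @export
grid_sample <- function(grid, points) field_at(grid, points)

#' Write a field grid as NIfTI (for fixtures and interoperability tests)
#' @param grid a `grid_field`.
#' @param path output `.nii` or `.nii.gz` path.
#' @export
write_field_grid <- function(grid, path) {
  img <- RNifti::asNifti(grid$field)
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
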