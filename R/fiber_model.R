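#' Fibre atlases as tidy tibbles
#'
#' A fibre atlas is a tibble with one row per streamline vertex and columns
#' `fiber_id`, `pathway`, `hemisphere`, `flagged`, `x`, `y`, `z` (mm, RAS).
#' Vertices of a fibre are consecutive rows in traversal order.  The
#' coordinate frame identifier is carried in the `space_tag` attribute and
#' the mid-sagittal plane is assumed at x = 0.
#'
#' @param df data frame with at least `fiber_id`, `x`, `y`, `z`; `pathway`,
#'   `hemisphere` and `flagged` are filled with defaults when absent.
#' @param space_tag coordinate frame label, default `"synthetic-ras"`.
#' @return a `fiber_atlas` tibble.
#' @export
as_fiber_atlas <- function(df, space_tag = "synthetic-ras") {
  need <- c("fiber_id", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste0("fiber atlas is missing columns: ", paste(miss, collapse = ", ")))
  }
  out <- tibble::as_tibble(df)
  if (!"pathway" %in% names(out)) out$pathway <- "unlabelled"
  if (!"hemisphere" %in% names(out)) out$hemisphere <- ifelse(out$x < 0, "left", "right")
  if (!"flagged" %in% names(out)) out$flagged <- FALSE
  out$fiber_id <- as.integer(out$fiber_id)
  validate_fiber_atlas(out)
  out <- out[, c("fiber_id", "pathway", "hemisphere", "flagged", "x", "y", "z")]
  attr(out, "space_tag") <- space_tag
  class(out) <- c("fiber_atlas", class(tibble::tibble()))
  out
}

validate_fiber_atlas <- function(df) {
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z))) {
    abort("fiber coordinates must be finite")
  }
  if (!all(df$hemisphere %in% c("left", "right"))) {
    abort("hemisphere must be 'left' or 'right'")
  }
  counts <- table(df$fiber_id)
  if (any(counts < 2)) {
    abort(paste0("fibers with fewer than 2 points: ",
                 paste(names(counts)[counts < 2], collapse = ", ")))
  }
  dup <- df |>
    dplyr::group_by(.data$fiber_id) |>
    dplyr::summarise(
      dup = any(diff(.data$x)^2 + diff(.data$y)^2 + diff(.data$z)^2 == 0),
      many_lab = dplyr::n_distinct(.data$pathway) > 1 ||
        dplyr::n_distinct(.data$hemisphere) > 1)
  if (any(dup$dup)) {
    abort(paste0("duplicate consecutive points in fiber(s): ",
                 paste(dup$fiber_id[dup$dup], collapse = ", ")))
  }
  if (any(dup$many_lab)) {
    abort("each fiber must carry a single pathway and hemisphere label")
  }
  invisible(df)
}

#' Per-fibre metadata (one row per fibre)
#' @param atlas a `fiber_atlas`.
#' @return tibble with fiber_id, pathway, hemisphere, flagged, n_points, length_mm.
#' @export
fiber_info <- function(atlas) {
  atlas |>
    dplyr::group_by(.data$fiber_id) |>
    dplyr::summarise(
      pathway = .data$pathway[1], hemisphere = .data$hemisphere[1],
      flagged = .data$flagged[1], n_points = dplyr::n(),
      length_mm = sum(sqrt(diff(.data$x)^2 + diff(.data$y)^2 + diff(.data$z)^2)))
}

fiber_points_matrix <- function(atlas, id) {
  sub <- atlas[atlas$fiber_id == id, , drop = FALSE]
  if (nrow(sub) == 0) abort(paste0("unknown fiber_id: ", id))
  as.matrix(sub[, c("x", "y", "z")])
}

arc_lengths <- function(pts) {
  c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
}

#' Read a fibre atlas
#'
#' The native format is a tab-separated table `<stem>.fib.tsv` with columns
#' `x`, `y`, `z`, `fiber_id` plus a JSON sidecar `<stem>.fib.json` mapping
#' each fiber_id to its pathway, hemisphere and flagged status.  MRtrix TCK
#' track files are also read (labels must then be supplied, as TCK carries
#' none).
#'
#' @param path path to the `.fib.tsv` (or its stem) or a `.tck` file.
#' @param format `"native"` or `"tck"`; guessed from the extension.
#' @param pathway,hemisphere labels applied to all fibres of a TCK file.
#' @return a `fiber_atlas` tibble.
#' @export
read_fibers <- function(path, format = NULL,
                        pathway = "unlabelled", hemisphere = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.tck$", path, ignore.case = TRUE)) "tck" else "native"
  }
  format <- match.arg(format, c("native", "tck"))
  if (format == "tck") return(read_tck(path, pathway, hemisphere))

  stem <- sub("\\.fib\\.tsv$", "", path)
  tsv <- paste0(stem, ".fib.tsv")
  sidecar <- paste0(stem, ".fib.json")
  if (!file.exists(tsv)) abort(paste0("no such file: ", tsv))
  if (!file.exists(sidecar)) abort(paste0("missing sidecar: ", sidecar))

  df <- tryCatch(
    readr::read_tsv(tsv, col_types = readr::cols(
      x = readr::col_double(), y = readr::col_double(),
      z = readr::col_double(), fiber_id = readr::col_integer())),
    error = function(e) abort(paste0("parse error in ", tsv, ": ", conditionMessage(e))))
  prob <- readr::problems(df)
  if (nrow(prob) > 0) {
    abort(paste0("malformed row(s) in ", tsv, " at line(s): ",
                 paste(unique(prob$row), collapse = ", ")))
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = FALSE)
  labels <- meta$fibers
  ids <- unique(df$fiber_id)
  missing_ids <- setdiff(as.character(ids), names(labels))
  if (length(missing_ids) > 0) {
    abort(paste0("fiber_id(s) absent from sidecar: ",
                 paste(missing_ids, collapse = ", ")))
  }
  lab <- tibble::tibble(
    fiber_id = as.integer(names(labels)),
    pathway = unname(purrr::map_chr(labels, "pathway")),
    hemisphere = unname(purrr::map_chr(labels, "hemisphere")),
    flagged = unname(purrr::map_lgl(labels, ~ isTRUE(.x$flagged))))
  out <- dplyr::left_join(df, lab, by = "fiber_id")
  as_fiber_atlas(out, space_tag = meta$space_tag %||% "unknown")
}

#' Write a fibre atlas in the native TSV + JSON sidecar format
#'
#' @param atlas a `fiber_atlas`; must be non-empty.
#' @param path output stem or `.fib.tsv` path.
#' @return the `.fib.tsv` path, invisibly usable in pipelines.
#' @export
write_fibers <- function(atlas, path) {
  if (nrow(atlas) == 0) abort("refusing to write an empty atlas")
  stem <- sub("\\.fib\\.tsv$", "", path)
  tsv <- paste0(stem, ".fib.tsv")
  sidecar <- paste0(stem, ".fib.json")
  df <- atlas[, c("x", "y", "z", "fiber_id")]
  df$x <- fmt_num(df$x); df$y <- fmt_num(df$y); df$z <- fmt_num(df$z)
  readr::write_tsv(df, tsv)
  info <- fiber_info(atlas)
  fibers <- setNames(
    purrr::pmap(info, function(fiber_id, pathway, hemisphere, flagged, ...) {
      list(pathway = pathway, hemisphere = hemisphere, flagged = flagged)
    }),
    as.character(info$fiber_id))
  jsonlite::write_json(
    list(space_tag = attr(atlas, "space_tag") %||% "unknown", fibers = fibers),
    sidecar, auto_unbox = TRUE, pretty = TRUE)
  tsv
}

# fixed 9-significant-digit text for byte-reproducible outputs
fmt_num <- function(x) formatC(signif(x, 9), format = "g", digits = 9)

# minimal MRtrix .tck reader: text header terminated by END, then
# float32 triplets with NaN fibre separators and Inf end-of-file marker
read_tck <- function(path, pathway, hemisphere) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^mrtrix tracks", magic)) abort("not a TCK file")
  offset <- NA; dtype <- "Float32LE"
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) abort("TCK header missing END")
    if (grepl("^END", line)) break
    kv <- strsplit(line, ":")[[1]]
    if (length(kv) >= 2) {
      key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = ":"))
      if (key == "file") offset <- as.integer(sub("^\\. ", "", val))
      if (key == "datatype") dtype <- val
    }
  }
  if (is.na(offset)) abort("TCK header lacks a file offset")
  endian <- if (grepl("BE$", dtype)) "big" else "little"
  seek(con, where = offset)
  raw <- readBin(con, what = "numeric", size = 4, n = file.size(path),
                 endian = endian)
  m <- matrix(raw, ncol = 3, byrow = TRUE)
  fid <- cumsum(is.nan(m[, 1])) + 1L
  keep <- !is.nan(m[, 1]) & !is.infinite(m[, 1])
  df <- tibble::tibble(fiber_id = fid[keep], x = m[keep, 1],
                       y = m[keep, 2], z = m[keep, 3])
  df$pathway <- pathway
  if (!is.null(hemisphere)) df$hemisphere <- hemisphere
  as_fiber_atlas(df, space_tag = "tck")
}

#' Resample fibres to uniform arc-length spacing
#'
#' Each fibre is re-sampled along its polyline at multiples of `step`;
#' the last segment may be shorter so that both endpoints are preserved.
#' Already-uniform fibres are reproduced exactly.
#'
#' @param atlas a `fiber_atlas` (or any tibble with the atlas columns).
#' @param step arc-length spacing in mm, default 0.5.
#' @return a resampled `fiber_atlas`.
#' @export
resample_fibers <- function(atlas, step = 0.5) {
  if (!is.numeric(step) || length(step) != 1 || step <= 0) {
    abort("resampling step must be a positive length in mm")
  }
  pieces <- lapply(split(atlas, atlas$fiber_id), function(sub) {
    pts <- as.matrix(sub[, c("x", "y", "z")])
    s <- arc_lengths(pts)
    total <- s[length(s)]
    si <- seq(0, total, by = step)
    if (si[length(si)] < total - 1e-12) si <- c(si, total)
    if (length(si) < 2) si <- c(0, total)
    tibble::tibble(
      fiber_id = sub$fiber_id[1], pathway = sub$pathway[1],
      hemisphere = sub$hemisphere[1], flagged = sub$flagged[1],
      x = approx(s, pts[, 1], xout = si)$y,
      y = approx(s, pts[, 2], xout = si)$y,
      z = approx(s, pts[, 3], xout = si)$y)
  })
  out <- dplyr::bind_rows(pieces)
  out <- out[order(match(out$fiber_id, unique(atlas$fiber_id))), ]
  as_fiber_atlas(out, space_tag = attr(atlas, "space_tag") %||% "unknown")
}

#' Unit tangent vectors along each fibre
#'
#' Central differences at interior vertices, one-sided at the endpoints,
#' normalised to unit length.
#'
#' @param atlas a `fiber_atlas`.
#' @return the atlas with tangent columns `tx`, `ty`, `tz` appended.
#' @export
fiber_tangents <- function(atlas) {
  tangent_one <- function(pts) {
    n <- nrow(pts)
    d <- rbind(pts[2, ] - pts[1, ],
               if (n > 2) pts[3:n, , drop = FALSE] - pts[1:(n - 2), , drop = FALSE],
               pts[n, ] - pts[n - 1, ])
    nn <- sqrt(rowSums(d^2))
    if (any(nn == 0)) abort("duplicate consecutive points: tangent undefined")
    d / nn
  }
  pieces <- lapply(split(atlas, atlas$fiber_id), function(sub) {
    tg <- tangent_one(as.matrix(sub[, c("x", "y", "z")]))
    sub$tx <- tg[, 1]; sub$ty <- tg[, 2]; sub$tz <- tg[, 3]
    sub
  })
  out <- dplyr::bind_rows(pieces)
  out[order(match(out$fiber_id, unique(atlas$fiber_id))), ]
}

#' Mirror an atlas across the mid-sagittal plane
#'
#' Negates x, swaps hemisphere labels, and offsets fiber_ids by the current
#' maximum id so the mirrored fibres can coexist with the originals.
#'
#' @param atlas a `fiber_atlas` with mid-sagittal plane at x = 0.
#' @param id_offset id shift for mirrored fibres; default `max(fiber_id)`.
#' @return the mirrored `fiber_atlas`.
#' @export
mirror_fibers <- function(atlas, id_offset = NULL) {
  off <- as.integer(id_offset %||% max(atlas$fiber_id))
  out <- atlas
  out$x <- -out$x
  out$hemisphere <- ifelse(out$hemisphere == "left", "right", "left")
  out$fiber_id <- out$fiber_id + off
  out <- as_fiber_atlas(out, space_tag = attr(atlas, "space_tag") %||% "unknown")
  attr(out, "mirror_offset") <- off
  out
}
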