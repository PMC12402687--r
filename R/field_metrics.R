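#' Metric configuration
#'
#' Bundles the choices that define a field-based activation metric: which
#' point-wise quantity is used (field magnitude or its projection onto the
#' fibre tangent), how point-wise values are aggregated along the fibre
#' (peak, sum or mean), the binarisation threshold in V/m, the sigmoid
#' slope used to convert fibre-wise values into activation probabilities,
#' and the along-fibre sampling step.
#'
#' Defaults: threshold 200 V/m for the magnitude and 125 V/m for the
#' projection metric; sigmoid slope anchored so that p = 0.5 at the
#' threshold and p = 0.95 at 1.5 times the threshold.
#'
#' @param metric `"magnitude"` or `"projection"`.
#' @param aggregator `"peak"` (default), `"sum"` or `"mean"`.
#' @param threshold binarisation threshold in V/m; `NULL` picks the
#'   metric-specific default.
#' @param sigmoid_slope logistic slope k in 1/(V/m); `NULL` anchors
#'   p = 0.95 at 1.5 threshold.
#' @param step_mm along-fibre sampling step, default 0.5 mm.
#' @param signed use the signed projection E.t instead of |E.t|; off by
#'   default so both field metrics are polarity-agnostic.
#' @return a `metric_config` list.
#' @export
metric_config <- function(metric = c("magnitude", "projection"),
                          aggregator = c("peak", "sum", "mean"),
                          threshold = NULL, sigmoid_slope = NULL,
                          step_mm = 0.5, signed = FALSE) {
  metric <- match.arg(metric)
  aggregator <- match.arg(aggregator)
  if (is.null(threshold)) threshold <- if (metric == "magnitude") 200 else 125
  if (threshold <= 0) abort("threshold must be > 0 (V/m)")
  if (is.null(sigmoid_slope)) sigmoid_slope <- log(19) / (0.5 * threshold)
  structure(list(metric = metric, aggregator = aggregator,
                 threshold = threshold, sigmoid_slope = sigmoid_slope,
                 step_mm = step_mm, signed = signed),
            class = "metric_config")
}

#' Point-wise field metrics along fibres
#'
#' Resamples each fibre at `step` mm, estimates unit tangents, samples the
#' field model, and reports per vertex the extracellular potential, the
#' field magnitude \eqn{\|E\|} and the tangential projection
#' \eqn{|E \cdot \hat t|} (absolute by default; axonal polarisation depends
#' on the field component parallel to the fibre, and the unsigned form
#' keeps the metric independent of both stimulus polarity and fibre
#' point-order).
#'
#' @param atlas a `fiber_atlas` (one or many fibres).
#' @param field a `point_source_field` or `grid_field`.
#' @param step along-fibre sampling step in mm.
#' @param signed keep the sign of the dot product.
#' @return tibble `fiber_id`, `pathway`, `arc_mm`, `potential_v`,
#'   `magnitude`, `projection` (V/m), one row per sample point.
#' @export
pointwise_metrics <- function(atlas, field, step = 0.5, signed = FALSE) {
  rs <- resample_fibers(atlas, step = step)
  rs <- fiber_tangents(rs)
  fs <- field_at(field, rs[, c("x", "y", "z")])
  proj <- fs$ex * rs$tx + fs$ey * rs$ty + fs$ez * rs$tz
  out <- rs |>
    dplyr::group_by(.data$fiber_id) |>
    dplyr::mutate(arc_mm = c(0, cumsum(sqrt(diff(.data$x)^2 +
                                              diff(.data$y)^2 +
                                              diff(.data$z)^2)))) |>
    dplyr::ungroup()
  out$potential_v <- fs$potential_v
  out$magnitude <- sqrt(fs$ex^2 + fs$ey^2 + fs$ez^2)
  out$projection <- if (signed) proj else abs(proj)
  out[, c("fiber_id", "pathway", "arc_mm", "potential_v",
          "magnitude", "projection")]
}

#' Aggregate point-wise values into one fibre-wise value
#'
#' @param values numeric vector of point-wise metric values for one fibre.
#' @param aggregator `"peak"`, `"sum"` or `"mean"`.
#' @return a scalar.
#' @export
aggregate_fiber_value <- function(values, aggregator = c("peak", "sum", "mean")) {
  aggregator <- match.arg(aggregator)
  if (length(values) == 0) abort("cannot aggregate an empty point series")
  switch(aggregator, peak = max(values), sum = sum(values), mean = mean(values))
}

#' Sigmoid activation probability for a fibre-wise field value
#'
#' \eqn{p(A) = 1 / (1 + \exp(-k (v - \theta)))} with midpoint
#' \eqn{\theta} at the binarisation threshold.  With the default slope,
#' p = 0.5 at the threshold and p = 0.95 at 1.5 times the threshold, a
#' soft surrogate for the spread of activation thresholds across axonal
#' morphologies.
#'
#' @param value fibre-wise metric value(s), >= 0.
#' @param threshold sigmoid midpoint in the units of `value`.
#' @param slope logistic slope; `NULL` for the default anchoring.
#' @return probabilities in (0, 1).
#' @export
sigmoid_probability <- function(value, threshold, slope = NULL) {
  if (any(value < 0)) abort("field metric values must be >= 0")
  if (threshold <= 0) abort("threshold must be > 0")
  k <- slope %||% (log(19) / (0.5 * threshold))
  1 / (1 + exp(-k * (value - threshold)))
}

#' Binary activation call for a fibre-wise field value
#'
#' Closed on the left: `value >= threshold` counts as activated.
#'
#' @inheritParams sigmoid_probability
#' @return logical vector.
#' @export
binarize_metric <- function(value, threshold) {
  value >= threshold
}

#' Fibre-wise metric table for one stimulation
#'
#' The full field-metric pipeline for an atlas: point-wise metrics,
#' aggregation, sigmoid probability and binary call, one row per fibre.
#'
#' @param atlas a `fiber_atlas`.
#' @param field a field model.
#' @param config a [metric_config()].
#' @return tibble of class `fiber_metrics`: `fiber_id`, `pathway`,
#'   `metric`, `aggregator`, `value`, `probability`, `binary`.
#' @export
fiber_metrics <- function(atlas, field, config = metric_config()) {
  pw <- pointwise_metrics(atlas, field, step = config$step_mm,
                          signed = config$signed)
  channel <- if (config$metric == "magnitude") "magnitude" else "projection"
  out <- pw |>
    dplyr::group_by(.data$fiber_id) |>
    dplyr::summarise(
      pathway = .data$pathway[1],
      value = aggregate_fiber_value(.data[[channel]], config$aggregator)) |>
    dplyr::mutate(
      metric = config$metric, aggregator = config$aggregator,
      probability = sigmoid_probability(abs(.data$value), config$threshold,
                                        config$sigmoid_slope),
      binary = binarize_metric(abs(.data$value), config$threshold)) |>
    dplyr::select("fiber_id", "pathway", "metric", "aggregator",
                  "value", "probability", "binary")
  class(out) <- c("fiber_metrics", class(out))
  out
}

#' Discrete activating function along a fibre
#'
#' Second central difference of the extracellular potential along the
#' fibre, \eqn{f_i = (V_{i-1} - 2 V_i + V_{i+1}) / h^2}, with the ends set
#' to zero.  Positive lobes predict sites of passive depolarisation; used
#' here as an independent cross-check of the cable model, not as a
#' headline metric.
#'
#' @param series output of [pointwise_metrics()] for a single fibre (or a
#'   tibble with `arc_mm` and `potential_v`), at uniform arc spacing.
#' @return numeric vector, V/mm^2, same length as the series.
#' @export
activating_function <- function(series) {
  if (nrow(series) < 3) abort("activating function needs >= 3 points")
  if ("fiber_id" %in% names(series) &&
      length(unique(series$fiber_id)) > 1) {
    abort("activating_function expects a single fibre")
  }
  h <- diff(series$arc_mm)
  if (max(h) - min(h) > 1e-6 * max(h)) {
    abort("activating function requires uniform arc spacing; resample first")
  }
  v <- series$potential_v
  n <- length(v)
  f <- numeric(n)
  f[2:(n - 1)] <- (v[1:(n - 2)] - 2 * v[2:(n - 1)] + v[3:n]) / mean(h)^2
  f
}
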