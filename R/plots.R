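#' Plot a fibre atlas projection
#'
#' 2-D orthographic projection of the atlas coloured by pathway, with
#' optional electrode contacts overlaid — the quick-look figure for
#' synthetic geometry.
#'
#' @param atlas a `fiber_atlas`.
#' @param plane `"xz"`, `"xy"` or `"yz"`.
#' @param electrode optional [make_electrode()] lead to overlay.
#' @return a ggplot object.
#' @export
plot_fibers <- function(atlas, plane = c("xz", "xy", "yz"),
                        electrode = NULL) {
  plane <- match.arg(plane)
  ax <- strsplit(plane, "")[[1]]
  p <- ggplot2::ggplot(atlas,
                       ggplot2::aes(.data[[ax[1]]], .data[[ax[2]]],
                                    group = .data$fiber_id,
                                    colour = .data$pathway)) +
    ggplot2::geom_path(alpha = 0.6, linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste0(ax[1], " (mm)"), y = paste0(ax[2], " (mm)"),
                  colour = "pathway") +
    ggplot2::theme_minimal()
  if (!is.null(electrode)) {
    p <- p + ggplot2::geom_point(
      data = electrode$contacts, inherit.aes = FALSE,
      ggplot2::aes(.data[[ax[1]]], .data[[ax[2]]]),
      shape = 15, size = 2, colour = "black")
  }
  p
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.fiber_metrics <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$value, .data$probability,
                                       colour = .data$pathway)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = sprintf("fibre-wise %s (%s, V/m)",
                              object$metric[1], object$aggregator[1]),
                  y = "activation probability p(A)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ppam_result <- function(object, ...) {
  df <- object[!is.na(object$p_a), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$p_a, fill = .data$pathway)) +
    ggplot2::geom_histogram(binwidth = 0.1, boundary = 0,
                            position = "stack") +
    ggplot2::labs(x = "activation certainty p(A) = N_activated / N_samples",
                  y = "fibres") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.activation_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$pathway, .data$pct_activated)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(y = "% fibres activated", x = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.topk_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$pathway, .data$n_fibers)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(y = "fibres among the top T-values", x = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fiber_stats <- function(object, ...) {
  df <- object[!is.na(object$t), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$t)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::labs(x = "fibre-wise T-value", y = "fibres") +
    ggplot2::theme_minimal()
}

#' Broom-style accessors
#'
#' `tidy()` returns the estimate-level table of a comparison or statistic
#' object; `glance()` a one-row model summary.
#'
#' @param x object to summarise.
#' @param ... unused.
#' @return a tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.profile_comparison <- function(x, ...) {
  tibble::tibble(estimate = x$rho, statistic = "spearman_rho",
                 p.value = x$p_value, n = x$n_pathways)
}

#' @rdname tidiers
#' @export
glance.profile_comparison <- function(x, ...) {
  tibble::tibble(rho = x$rho, p.value = x$p_value,
                 n.pathways = x$n_pathways,
                 significant = x$p_value < 0.05)
}

#' @rdname tidiers
#' @export
tidy.fiber_stats <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidiers
#' @export
glance.fiber_stats <- function(x, ...) {
  tibble::tibble(n.fibers = nrow(x),
                 n.defined = sum(!is.na(x$t)),
                 max.t = suppressWarnings(max(x$t, na.rm = TRUE)),
                 mean.t = mean(x$t, na.rm = TRUE))
}

#' @rdname tidiers
#' @export
glance.ppam_result <- function(x, ...) {
  ok <- !is.na(x$p_a)
  tibble::tibble(n.fibers = nrow(x),
                 n.simulated = sum(x$n_samples > 0, na.rm = TRUE),
                 mean.p_a = mean(x$p_a[ok]),
                 frac.certain = mean(x$p_a[ok] == 1))
}
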