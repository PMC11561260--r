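#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ECDF ambiguity curve
#'
#' One cumulative curve per reference group with the probability threshold
#' as a dashed vertical line.
#'
#' @param object An [ecdf_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ecdf_curve
#' @export
autoplot.ecdf_curve <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$value, y = .data$frac,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = sprintf("Prob(%s)", object$target_type),
                  y = "cumulative fraction", colour = "reference type") +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Plot an overlap matrix as a heatmap
#'
#' @param object An [overlap_matrix()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot overlap_matrix
#' @export
autoplot.overlap_matrix <- function(object, ...) {
  long <- tidy.overlap_matrix(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$predicted_label,
                                     y = .data$reference_label,
                                     fill = .data$proportion)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$proportion)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "predicted", y = "reference") +
    ggplot2::theme_minimal()
}

#' Plot the fate-bias distribution with the hybrid window shaded
#'
#' @param object A [fate_bias()] result.
#' @param window Hybrid window to shade.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fate_bias
#' @export
autoplot.fate_bias <- function(object, window = c(0.4, 0.6), bins = 40, ...) {
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(x = .data$bias)) +
    ggplot2::annotate("rect", xmin = window[1], xmax = window[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "orange") +
    ggplot2::geom_histogram(bins = bins, boundary = 0) +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(x = sprintf("fate bias (%s vs %s)", attr(object, "type_a"),
                              attr(object, "type_b")),
                  y = "cells") +
    ggplot2::theme_minimal()
}

#' Stacked-bar comparison of baseline vs perturbed cell-type fractions
#'
#' @param object A `perturbation_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot perturbation_result
#' @export
autoplot.perturbation_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$fractions, c("baseline", "perturbed"),
                              names_to = "run", values_to = "fraction")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$run, y = .data$fraction,
                                     fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(title = sprintf("knockout: %s", object$gene_set),
                  x = NULL, y = "fraction of cells") +
    ggplot2::theme_minimal()
}
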