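#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fate-bias result
#'
#' @param x A [fate_bias()] result.
#' @param ... Unused.
#' @return A tibble with `cell_id`, `prob_a`, `prob_b`, `bias` plus the
#'   pair as columns.
#' @method tidy fate_bias
#' @export
tidy.fate_bias <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x),
                type_a = attr(x, "type_a"), type_b = attr(x, "type_b"))
}

#' @rdname tidy.fate_bias
#' @param window Hybrid window summarised by `glance()`.
#' @method glance fate_bias
#' @export
glance.fate_bias <- function(x, window = c(0.4, 0.6), ...) {
  tibble::tibble(
    type_a = attr(x, "type_a"), type_b = attr(x, "type_b"),
    m = nrow(x), n_excluded = length(attr(x, "excluded")),
    n_hybrid = sum(x$bias >= window[1] & x$bias <= window[2]),
    phc = phc(x, window),
    mean_bias = mean(x$bias), median_bias = stats::median(x$bias)
  )
}

#' Tidy a trained classifier's coefficients
#'
#' @param x A `plasticity_classifier`.
#' @param ... Unused.
#' @return A tibble with `class`, `term`, `estimate` at the model's fixed
#'   penalty.
#' @method tidy plasticity_classifier
#' @export
tidy.plasticity_classifier <- function(x, ...) {
  s <- x$hyperparams$lambda
  purrr::map_dfr(x$classes, function(cl) {
    b <- as.matrix(predict(x$fit, type = "coefficients", s = s)[[cl]])
    tibble::tibble(class = cl, term = rownames(b), estimate = b[, 1])
  })
}

#' @rdname tidy.plasticity_classifier
#' @method glance plasticity_classifier
#' @export
glance.plasticity_classifier <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$classes),
    n_features = if (x$feature_spec$kind == "gene_sets")
      length(x$feature_spec$sets) else length(x$feature_spec$genes),
    feature_kind = x$feature_spec$kind,
    n_train = x$training_log$n_cells,
    holdout_accuracy = x$training_log$holdout_accuracy,
    lambda = x$hyperparams$lambda
  )
}

#' Tidy an overlap matrix into long format
#'
#' @param x An [overlap_matrix()].
#' @param ... Unused.
#' @return A tibble with `reference_label`, `predicted_label`,
#'   `proportion`.
#' @method tidy overlap_matrix
#' @export
tidy.overlap_matrix <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"reference_label",
                      names_to = "predicted_label", values_to = "proportion")
}

#' @rdname tidy.overlap_matrix
#' @method glance overlap_matrix
#' @export
glance.overlap_matrix <- function(x, ...) {
  long <- tidy.overlap_matrix(x)
  diag <- dplyr::filter(long, .data$reference_label == .data$predicted_label)
  tibble::tibble(n_types = nrow(x),
                 n_flagged = length(attr(x, "flagged_types")),
                 min_diagonal = if (nrow(diag) > 0) min(diag$proportion) else 0,
                 flag_threshold = attr(x, "flag_threshold"))
}

#' Tidy an ECDF curve's points
#'
#' @param x An [ecdf_curve()].
#' @param ... Unused.
#' @method tidy ecdf_curve
#' @export
tidy.ecdf_curve <- function(x, ...) x$points

#' @rdname tidy.ecdf_curve
#' @method glance ecdf_curve
#' @export
glance.ecdf_curve <- function(x, ...) {
  dplyr::mutate(x$threshold_fractions, target_type = x$target_type,
                threshold = x$threshold)
}
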