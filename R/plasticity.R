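#' Per-cell fate bias for an ordered type pair
#'
#' For each eligible cell, the fate bias of type A against type B is
#' `Prob.A / (Prob.A + Prob.B)`: 1 means definite commitment to A, 0
#' definite commitment to B, and 0.5 an equal ("hybrid") state. The signed
#' variant `(Prob.A - Prob.B) / (Prob.A + Prob.B)` is available for audit
#' via `method = "signed"`.
#'
#' The eligible population M defaults to cells whose `reference_label` is A
#' or B when a cell table is given, or to all cells otherwise; an explicit
#' cell-id vector overrides both. Cells with `Prob.A + Prob.B = 0` carry no
#' information about the pair and are excluded from M (recorded in the
#' result).
#'
#' @param prob A [prob_matrix()].
#' @param type_a,type_b Distinct class labels (the ordered pair).
#' @param cells Optional cell table; restricts M to reference labels A or B.
#' @param eligible Optional explicit character vector of cell ids defining M.
#' @param method `"ratio"` (default) or `"signed"`.
#' @return A `fate_bias` tibble (`cell_id`, `prob_a`, `prob_b`, `bias`) with
#'   attributes `type_a`, `type_b`, `method` and `excluded` (cell ids
#'   dropped for zero joint probability).
#' @export
fate_bias <- function(prob, type_a, type_b, cells = NULL, eligible = NULL,
                      method = c("ratio", "signed")) {
  stopifnot(inherits(prob, "prob_matrix"))
  method <- match.arg(method)
  cls <- prob_classes(prob)
  for (ty in c(type_a, type_b)) {
    if (!ty %in% cls) {
      stop(sprintf("unknown class label '%s'", ty), call. = FALSE)
    }
  }
  if (identical(type_a, type_b)) stop("type_a and type_b must differ", call. = FALSE)
  ids <- prob$cell_id
  if (!is.null(eligible)) {
    keep <- ids %in% eligible
  } else if (!is.null(cells)) {
    in_pair <- cells$cell_id[cells$reference_label %in% c(type_a, type_b)]
    keep <- ids %in% in_pair
  } else {
    keep <- rep(TRUE, length(ids))
  }
  if (!any(keep)) stop("eligible cell set is empty", call. = FALSE)
  pa <- prob[[type_a]][keep]
  pb <- prob[[type_b]][keep]
  ids <- ids[keep]
  zero <- (pa + pb) < 1e-12
  excluded <- ids[zero]
  if (all(zero)) {
    stop("all eligible cells have zero joint probability for the pair",
         call. = FALSE)
  }
  pa <- pa[!zero]; pb <- pb[!zero]; ids <- ids[!zero]
  bias <- if (method == "ratio") pa / (pa + pb) else (pa - pb) / (pa + pb)
  out <- tibble::tibble(cell_id = ids, prob_a = pa, prob_b = pb, bias = bias)
  structure(out, type_a = type_a, type_b = type_b, method = method,
            excluded = excluded, class = c("fate_bias", class(out)))
}

#' Proportion of hybrid cells in a bias window
#'
#' `P_hc = N / M` where N is the number of eligible cells whose fate bias
#' lies in the closed window (default the hybrid window \[0.4, 0.6\]) and M
#' the eligible total. Reported as a proportion; multiply by 100 for the
#' percentage form used in output tables.
#'
#' @param result A [fate_bias()] result.
#' @param window Closed interval within \[0, 1\].
#' @return A single proportion in \[0, 1\].
#' @export
phc <- function(result, window = c(0.4, 0.6)) {
  stopifnot(inherits(result, "fate_bias"))
  check_window(window)
  m <- nrow(result)
  if (m == 0) stop("M = 0: no eligible cells", call. = FALSE)
  sum(result$bias >= window[1] & result$bias <= window[2]) / m
}

check_window <- function(window) {
  if (length(window) != 2 || !is.numeric(window) || anyNA(window) ||
      window[1] > window[2] || window[1] < 0 || window[2] > 1) {
    stop("window must be a closed interval [lo, hi] within [0, 1]",
         call. = FALSE)
  }
  invisible(window)
}

#' P_hc summary table over pairs, windows and groups
#'
#' One row per (group, window), one column per ordered pair, mirroring the
#' usual presentation: percentages rounded to 2 decimals. Eligibility per
#' pair is reference-label membership within the group.
#'
#' @param prob A [prob_matrix()].
#' @param cells Cell table (`cell_id`, `reference_label`, `group`).
#' @param pairs List of length-2 character vectors `c(A, B)`.
#' @param windows List of closed intervals; default the three standard
#'   hybrid windows.
#' @return A tibble with columns `group`, `window`, then one percentage
#'   column per pair named `"A vs B"`.
#' @export
phc_table <- function(prob, cells,
                      pairs = list(c("HSC", "GMP"), c("HSC", "MEP"),
                                   c("GMP", "MEP"), c("GMP", "Pro_NE")),
                      windows = list(c(0.35, 0.65), c(0.4, 0.6),
                                     c(0.45, 0.55))) {
  stopifnot(inherits(prob, "prob_matrix"))
  lapply(windows, check_window)
  groups <- unique(cells$group)
  rows <- purrr::map_dfr(groups, function(g) {
    gcells <- dplyr::filter(cells, .data$group == g)
    gprob <- prob[prob$cell_id %in% gcells$cell_id, ]
    class(gprob) <- class(prob)
    attr(gprob, "class_labels") <- prob_classes(prob)
    purrr::map_dfr(windows, function(w) {
      vals <- purrr::map_dbl(pairs, function(p) {
        fb <- fate_bias(gprob, p[1], p[2], cells = gcells)
        round(100 * phc(fb, w), 2)
      })
      out <- tibble::tibble(group = g,
                            window = sprintf("[%g, %g]", w[1], w[2]))
      out[vapply(pairs, function(p) paste(p[1], "vs", p[2]), character(1))] <-
        as.list(vals)
      out
    })
  })
  rows
}

#' ECDF ambiguity curves for one target type
#'
#' Empirical cumulative distribution of the probability of being the target
#' type, computed within each reference-label group, plus the fraction of
#' each group's cells with probability strictly below the threshold
#' (default 0.5) — the scalar ambiguity summary.
#'
#' @param prob A [prob_matrix()].
#' @param target_type Class label whose probability column is analysed.
#' @param cells Cell table supplying the grouping (`reference_label`).
#' @param threshold Probability threshold (vertical reference line).
#' @return An `ecdf_curve`: list with `points` (tibble `group`, `value`,
#'   `frac`), `threshold_fractions` (tibble `group`, `n`, `frac_below`),
#'   `target_type`, `threshold`.
#' @export
ecdf_curve <- function(prob, target_type, cells, threshold = 0.5) {
  stopifnot(inherits(prob, "prob_matrix"))
  if (!target_type %in% prob_classes(prob)) {
    stop(sprintf("unknown class label '%s'", target_type), call. = FALSE)
  }
  df <- dplyr::inner_join(
    tibble::tibble(cell_id = prob$cell_id, p = prob[[target_type]]),
    cells[, c("cell_id", "reference_label")], by = "cell_id"
  )
  absent <- setdiff(unique(cells$reference_label), df$reference_label)
  if (length(absent) > 0) {
    warning(sprintf("omitting empty group(s): %s",
                    paste(absent, collapse = ", ")), call. = FALSE)
  }
  points <- df |>
    dplyr::group_by(group = .data$reference_label) |>
    dplyr::arrange(.data$p, .by_group = TRUE) |>
    dplyr::mutate(value = .data$p,
                  frac = seq_len(dplyr::n()) / dplyr::n()) |>
    dplyr::ungroup() |>
    dplyr::select("group", "value", "frac")
  thr <- df |>
    dplyr::group_by(group = .data$reference_label) |>
    dplyr::summarise(n = dplyr::n(), frac_below = mean(.data$p < threshold),
                     .groups = "drop")
  structure(list(points = points, threshold_fractions = thr,
                 target_type = target_type, threshold = threshold),
            class = "ecdf_curve")
}

#' @export
print.ecdf_curve <- function(x, ...) {
  cat(sprintf("<ecdf_curve> Prob(%s) across %d groups, threshold %.2f\n",
              x$target_type, nrow(x$threshold_fractions), x$threshold))
  print(x$threshold_fractions)
  invisible(x)
}

#' Reference-vs-prediction overlap matrix
#'
#' Row-normalised confusion matrix between reference annotation and hard
#' predicted labels: entry (r, p) is the fraction of reference-r cells
#' predicted as p, so every row sums to 1. Reference types whose diagonal
#' entry falls below `flag_threshold` are flagged as fate-flexible.
#'
#' @param cells Cell table (reference labels).
#' @param predicted Output of [assign_labels()] (tibble `cell_id`,
#'   `predicted_label`), or a character vector named by cell id.
#' @param flag_threshold Diagonal threshold below which a type is flagged.
#' @return An `overlap_matrix`: wide tibble (first column
#'   `reference_label`, one column per predicted label) with attribute
#'   `flagged_types`.
#' @export
overlap_matrix <- function(cells, predicted, flag_threshold = 0.8) {
  if (is.character(predicted)) {
    predicted <- tibble::tibble(cell_id = names(predicted),
                                predicted_label = unname(predicted))
  }
  if (!setequal(cells$cell_id, predicted$cell_id)) {
    stop("reference and prediction must cover the same cells", call. = FALSE)
  }
  df <- dplyr::inner_join(cells[, c("cell_id", "reference_label")],
                          predicted, by = "cell_id")
  ref_labels <- sort(unique(df$reference_label))
  pred_labels <- sort(unique(df$predicted_label))
  if (length(intersect(ref_labels, pred_labels)) == 0) {
    stop("reference and predicted label sets are disjoint", call. = FALSE)
  }
  tab <- table(factor(df$reference_label, ref_labels),
               factor(df$predicted_label, pred_labels))
  m <- unclass(tab / rowSums(tab))
  out <- dplyr::bind_cols(tibble::tibble(reference_label = ref_labels),
                          tibble::as_tibble(m))
  diag_entry <- vapply(ref_labels, function(r) {
    if (r %in% pred_labels) m[r, r] else 0
  }, numeric(1))
  flagged <- ref_labels[diag_entry < flag_threshold]
  structure(out, flagged_types = flagged, flag_threshold = flag_threshold,
            class = c("overlap_matrix", class(out)))
}

#' @rdname overlap_matrix
#' @param x An `overlap_matrix`.
#' @export
flagged_types <- function(x) attr(x, "flagged_types")
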