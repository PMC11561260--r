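#' In-silico knockout: zero a gene set's expression
#'
#' Sets the raw counts of every gene in the set that is present in the
#' matrix to zero, leaving all other entries untouched. The knockout acts
#' on raw counts so that library-size factors are recomputed from the
#' post-knockout totals during normalisation. Idempotent.
#'
#' @param expr An `expr_matrix` with layer `raw_counts`.
#' @param genes Character vector of gene symbols (e.g. one set from a
#'   [gene_set_collection()]).
#' @param name Optional set name recorded on the result.
#' @return An `expr_matrix` (raw counts) with attributes `genes_hit`,
#'   `genes_missing` and `knockout`.
#' @export
knockout_gene_set <- function(expr, genes, name = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr_layer(expr) != "raw_counts") {
    stop("knockout must act on raw counts (before normalisation)",
         call. = FALSE)
  }
  genes <- unique(as.character(genes))
  hit <- intersect(genes, expr_genes(expr))
  miss <- setdiff(genes, hit)
  if (length(hit) == 0) {
    stop("nothing to knock out: no gene of the set is present in the matrix",
         call. = FALSE)
  }
  v <- expr_values(expr)
  v[, hit] <- 0
  v <- Matrix::drop0(v)
  out <- expression_matrix(v, layer = "raw_counts")
  attr(out, "genes_hit") <- hit
  attr(out, "genes_missing") <- miss
  attr(out, "knockout") <- name %||% NA_character_
  out
}

#' Knock out a gene set and re-predict cell identities
#'
#' The in-silico pathway knockout: zero the set's genes in the raw counts,
#' re-predict per-cell probabilities with the SAME trained model (never
#' retrained), and compare per-type fractions — and optionally per-pair
#' P_hc — against the unperturbed baseline.
#'
#' @param model A trained `plasticity_classifier`.
#' @param expr Query `expr_matrix` (raw counts).
#' @param genes Gene set to zero (character vector).
#' @param set_name Name recorded in the result.
#' @param cells Optional cell table; enables per-pair P_hc comparison.
#' @param pairs Optional list of `c(A, B)` pairs for P_hc.
#' @param window Hybrid window for P_hc, default `c(0.4, 0.6)`.
#' @param baseline Optional precomputed baseline [prob_matrix()] for `expr`
#'   under `model` (recomputed when `NULL`).
#' @return A `perturbation_result`: `gene_set`, `genes_hit`,
#'   `genes_missing`, `baseline_prob`, `perturbed_prob`, `fractions`
#'   (tibble `class`, `baseline`, `perturbed`; columns each sum to 1) and,
#'   when pairs are given, `phc` (tibble `pair`, `window`, `baseline`,
#'   `perturbed`).
#' @export
perturb_and_repredict <- function(model, expr, genes, set_name = "set",
                                  cells = NULL, pairs = NULL,
                                  window = c(0.4, 0.6), baseline = NULL) {
  stopifnot(inherits(model, "plasticity_classifier"))
  ko <- knockout_gene_set(expr, genes, name = set_name)
  if (is.null(baseline)) baseline <- predict_proba(model, expr)
  perturbed <- predict_proba(model, ko)
  frac_of <- function(p) {
    lab <- assign_labels(p)
    tab <- table(factor(lab$predicted_label, model$classes))
    as.numeric(tab / sum(tab))
  }
  fractions <- tibble::tibble(class = model$classes,
                              baseline = frac_of(baseline),
                              perturbed = frac_of(perturbed))
  phc_tbl <- NULL
  if (!is.null(pairs)) {
    check_window(window)
    phc_tbl <- purrr::map_dfr(pairs, function(p) {
      fb0 <- fate_bias(baseline, p[1], p[2], cells = cells)
      fb1 <- fate_bias(perturbed, p[1], p[2], cells = cells)
      phc0 <- phc(fb0, window)
      phc1 <- phc(fb1, window)
      tibble::tibble(pair = paste(p[1], "vs", p[2]),
                     window = sprintf("[%g, %g]", window[1], window[2]),
                     baseline = phc0, perturbed = phc1)
    })
  }
  structure(list(gene_set = set_name,
                 genes_hit = attr(ko, "genes_hit"),
                 genes_missing = attr(ko, "genes_missing"),
                 baseline_prob = baseline, perturbed_prob = perturbed,
                 fractions = fractions, phc = phc_tbl),
            class = "perturbation_result")
}

#' @export
print.perturbation_result <- function(x, ...) {
  cat(sprintf("<perturbation_result> knockout of '%s' (%d genes hit, %d missing)\n",
              x$gene_set, length(x$genes_hit), length(x$genes_missing)))
  print(x$fractions)
  if (!is.null(x$phc)) print(x$phc)
  invisible(x)
}

#' Classify the effect of a perturbation relative to two reference states
#'
#' Given the P_hc of a healthy control, a diseased condition, and the
#' perturbed run, the perturbation is `partially_reversed` when its value
#' lies in the closed interval between control and disease (boundary
#' equality inclusive, so float noise cannot flip a call), `reversed` when
#' it lies strictly beyond the control on the side away from the disease,
#' and `not_reversed` otherwise. The same rule applies to any paired scalar
#' in \[0, 1\], e.g. ECDF values at probability 0.5.
#'
#' @param control_phc,disease_phc,perturbed_phc Values in \[0, 1\].
#' @return One of `"reversed"`, `"partially_reversed"`, `"not_reversed"`.
#' @export
classify_reversal <- function(control_phc, disease_phc, perturbed_phc) {
  vals <- c(control = control_phc, disease = disease_phc,
            perturbed = perturbed_phc)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1)) {
    stop("all P_hc values must lie in [0, 1]", call. = FALSE)
  }
  lo <- min(control_phc, disease_phc)
  hi <- max(control_phc, disease_phc)
  if (perturbed_phc >= lo && perturbed_phc <= hi) {
    return("partially_reversed")
  }
  beyond_control <-
    (control_phc < disease_phc && perturbed_phc < control_phc) ||
    (control_phc > disease_phc && perturbed_phc > control_phc)
  if (beyond_control) "reversed" else "not_reversed"
}

#' Combine perturbation results into long-format report tables
#'
#' @param results A list of `perturbation_result` objects.
#' @return A list of tibbles: `fractions` (`gene_set`, `class`, `baseline`,
#'   `perturbed`) and `phc` (`gene_set`, `pair`, `window`, `baseline`,
#'   `perturbed`; `NULL` when no result carries P_hc).
#' @export
perturbation_report <- function(results) {
  if (length(results) == 0) stop("at least one result is required", call. = FALSE)
  stopifnot(all(vapply(results, inherits, logical(1), "perturbation_result")))
  fractions <- purrr::map_dfr(results, function(r)
    dplyr::mutate(r$fractions, gene_set = r$gene_set, .before = 1))
  phc_tbl <- purrr::map_dfr(results, function(r) {
    if (is.null(r$phc)) return(NULL)
    dplyr::mutate(r$phc, gene_set = r$gene_set, .before = 1)
  })
  list(fractions = fractions,
       phc = if (nrow(phc_tbl) > 0) phc_tbl else NULL)
}

#' Value of a group's ECDF at a probability threshold
#'
#' The scalar compared by the reversal rule in ECDF space: the fraction of
#' the group's cells whose target-type probability is strictly below the
#' threshold.
#'
#' @param curve An [ecdf_curve()].
#' @param group Reference group label.
#' @return A value in \[0, 1\].
#' @export
ecdf_value_at <- function(curve, group) {
  stopifnot(inherits(curve, "ecdf_curve"))
  row <- curve$threshold_fractions[curve$threshold_fractions$group == group, ]
  if (nrow(row) == 0) stop(sprintf("no group '%s' in curve", group), call. = FALSE)
  row$frac_below
}
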