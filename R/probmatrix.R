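#' Per-cell probability matrix over cell types
#'
#' The pipeline's central interchange object: one row per cell, one column
#' per class label, entries in \[0, 1\] with each row summing to 1. Stored as
#' a tibble with a `cell_id` column followed by one column per class, so it
#' pipes directly into the plasticity statistics.
#'
#' @param x A numeric matrix (cells x classes) or a data frame whose first
#'   column holds cell ids.
#' @param cell_ids,class_labels Identifiers; taken from dimnames / column
#'   names when omitted.
#' @param renorm_tol Rows whose sum deviates from 1 by at most this much are
#'   renormalised; larger deviations are an error. The constructor default
#'   (1e-6) is strict; the CSV reader uses 1e-3.
#'
#' @return A tibble of class `prob_matrix` with attribute `class_labels`.
#' @export
prob_matrix <- function(x, cell_ids = NULL, class_labels = NULL,
                        renorm_tol = 1e-6) {
  if (is.data.frame(x)) {
    cell_ids <- cell_ids %||% as.character(x[[1]])
    class_labels <- class_labels %||% names(x)[-1]
    x <- as.matrix(x[, -1, drop = FALSE])
  } else {
    x <- as.matrix(x)
    cell_ids <- cell_ids %||% rownames(x)
    class_labels <- class_labels %||% colnames(x)
  }
  if (is.null(cell_ids) || is.null(class_labels)) {
    stop("cell ids and class labels are required", call. = FALSE)
  }
  cell_ids <- as.character(cell_ids)
  class_labels <- as.character(class_labels)
  storage.mode(x) <- "double"
  if (length(cell_ids) != nrow(x) || length(class_labels) != ncol(x)) {
    stop("probability matrix dimensions do not match ids", call. = FALSE)
  }
  if (anyDuplicated(class_labels)) stop("class labels are not unique", call. = FALSE)
  if (anyDuplicated(cell_ids)) stop("cell ids are not unique", call. = FALSE)
  if (any(!is.finite(x))) stop("probabilities contain non-finite values", call. = FALSE)
  if (any(x < -1e-9) || any(x > 1 + 1e-9)) {
    bad <- which(x < -1e-9 | x > 1 + 1e-9, arr.ind = TRUE)[1, ]
    stop(sprintf("probability outside [0, 1] for cell '%s', class '%s'",
                 cell_ids[bad[1]], class_labels[bad[2]]), call. = FALSE)
  }
  x[x < 0] <- 0
  x[x > 1] <- 1
  rs <- rowSums(x)
  off <- abs(rs - 1) > renorm_tol
  if (any(off)) {
    stop(sprintf("row sum deviates from 1 by more than %g for cell '%s' (sum = %.6f)",
                 renorm_tol, cell_ids[which(off)[1]], rs[which(off)[1]]),
         call. = FALSE)
  }
  x <- x / rs
  out <- tibble::tibble(cell_id = cell_ids)
  out[class_labels] <- lapply(seq_along(class_labels),
                              function(j) unname(x[, j]))
  structure(out, class_labels = class_labels,
            class = c("prob_matrix", class(out)))
}

#' @rdname prob_matrix
#' @param p A `prob_matrix`.
#' @export
prob_classes <- function(p) attr(p, "class_labels")

#' @rdname prob_matrix
#' @export
prob_values <- function(p) {
  cls <- prob_classes(p)
  m <- as.matrix(as.data.frame(p)[, cls, drop = FALSE])
  rownames(m) <- p$cell_id
  m
}
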