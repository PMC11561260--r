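#' Validated cell-by-gene expression matrix
#'
#' Constructs the package's central expression container: a sparse
#' cells-by-genes matrix with unique cell and gene identifiers and a layer
#' tag recording whether the values are raw counts or log-normalised
#' expression. Cells are always rows.
#'
#' @param values A numeric matrix or `Matrix` sparse matrix, cells in rows,
#'   genes in columns. All entries must be non-negative and finite.
#' @param cell_ids Character vector of unique cell identifiers; defaults to
#'   `rownames(values)`.
#' @param gene_ids Character vector of unique gene identifiers; defaults to
#'   `colnames(values)`.
#' @param layer One of `"raw_counts"` or `"lognorm"`.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (a `dgCMatrix`, cells x genes, with dimnames) and `layer`.
#' @export
#' @examples
#' m <- matrix(c(5, 0, 1, 3, 2, 0), nrow = 3,
#'             dimnames = list(paste0("c", 1:3), c("g1", "g2")))
#' expression_matrix(m)
expression_matrix <- function(values, cell_ids = rownames(values),
                              gene_ids = colnames(values),
                              layer = c("raw_counts", "lognorm")) {
  layer <- match.arg(layer)
  if (is.null(cell_ids) || is.null(gene_ids)) {
    stop("cell_ids and gene_ids are required (as arguments or dimnames)",
         call. = FALSE)
  }
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values) || length(gene_ids) != ncol(values)) {
    stop(sprintf(
      "dimension mismatch: matrix is %d x %d but %d cell ids and %d gene ids were given",
      nrow(values), ncol(values), length(cell_ids), length(gene_ids)
    ), call. = FALSE)
  }
  if (anyDuplicated(cell_ids)) stop("cell ids are not unique", call. = FALSE)
  if (anyDuplicated(gene_ids)) stop("gene ids are not unique", call. = FALSE)
  x <- methods::as(methods::as(Matrix::Matrix(values, sparse = TRUE),
                               "CsparseMatrix"), "generalMatrix")
  if (any(!is.finite(x@x))) {
    stop("expression matrix contains non-finite values", call. = FALSE)
  }
  if (any(x@x < 0)) {
    stop(sprintf("expression matrix contains %d negative entries",
                 sum(x@x < 0)), call. = FALSE)
  }
  dimnames(x) <- list(cell_ids, gene_ids)
  structure(list(values = x, layer = layer), class = "expr_matrix")
}

#' Accessors for `expr_matrix` objects
#'
#' @param x An `expr_matrix`.
#' @return `expr_values()` the underlying `dgCMatrix` (cells x genes);
#'   `expr_layer()` the layer tag; `expr_cells()` / `expr_genes()` the
#'   identifier vectors.
#' @export
expr_values <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  x$values
}

#' @rdname expr_values
#' @export
expr_layer <- function(x) x$layer

#' @rdname expr_values
#' @export
expr_cells <- function(x) rownames(x$values)

#' @rdname expr_values
#' @export
expr_genes <- function(x) colnames(x$values)

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d cells x %d genes, layer = %s, %.1f%% nonzero\n",
              nrow(x$values), ncol(x$values), x$layer,
              100 * Matrix::nnzero(x$values) / prod(dim(x$values))))
  invisible(x)
}

#' Subset an expression matrix by cells and/or genes
#'
#' @param x An `expr_matrix`.
#' @param cells,genes Character vectors of identifiers (or indices) to keep;
#'   `NULL` keeps all.
#' @return A new `expr_matrix` with the same layer tag.
#' @export
expr_subset <- function(x, cells = NULL, genes = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  v <- x$values
  if (!is.null(cells)) v <- v[cells, , drop = FALSE]
  if (!is.null(genes)) v <- v[, genes, drop = FALSE]
  expression_matrix(v, layer = x$layer)
}
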