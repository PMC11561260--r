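#' Read an expression matrix from disk
#'
#' Reads either a Matrix Market `.mtx` triplet (matrix plus one-column cell
#' and gene id files, cells as rows) or a dense CSV (first column cell ids,
#' header gene ids). Sparse input stays sparse.
#'
#' @param matrix_path Path to a `.mtx` or `.csv` file.
#' @param cells_path,genes_path Paths to one-id-per-line text files; required
#'   for `.mtx`, ignored for `.csv`.
#' @param layer Layer tag recorded on the result.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(matrix_path, cells_path = NULL, genes_path = NULL,
                            layer = c("raw_counts", "lognorm")) {
  layer <- match.arg(layer)
  if (!file.exists(matrix_path)) {
    stop(sprintf("matrix file not found: %s", matrix_path), call. = FALSE)
  }
  if (grepl("\\.csv$", matrix_path, ignore.case = TRUE)) {
    df <- readr::read_csv(matrix_path, show_col_types = FALSE,
                          progress = FALSE)
    cell_ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    return(expression_matrix(m, cell_ids = cell_ids,
                             gene_ids = colnames(m), layer = layer))
  }
  if (is.null(cells_path) || is.null(genes_path)) {
    stop("cells_path and genes_path are required for .mtx input", call. = FALSE)
  }
  for (p in c(cells_path, genes_path)) {
    if (!file.exists(p)) stop(sprintf("id file not found: %s", p), call. = FALSE)
  }
  m <- Matrix::readMM(matrix_path)
  cell_ids <- readLines(cells_path)
  gene_ids <- readLines(genes_path)
  cell_ids <- cell_ids[nzchar(cell_ids)]
  gene_ids <- gene_ids[nzchar(gene_ids)]
  if (nrow(m) != length(cell_ids) || ncol(m) != length(gene_ids)) {
    stop(sprintf(
      "dimension mismatch: matrix is %d x %d but %d cell ids and %d gene ids were given",
      nrow(m), ncol(m), length(cell_ids), length(gene_ids)), call. = FALSE)
  }
  expression_matrix(m, cell_ids = cell_ids, gene_ids = gene_ids, layer = layer)
}

#' Write an expression matrix to disk
#'
#' Writes `<basename>.mtx` + `<basename>_cells.tsv` + `<basename>_genes.tsv`
#' (or a single dense CSV) into `dir` and returns a manifest of paths,
#' shapes and md5 checksums.
#'
#' @param x An `expr_matrix`.
#' @param dir Output directory (created if missing).
#' @param basename File stem.
#' @param format `"mtx"` or `"csv"`.
#' @return Invisibly, a manifest list (`paths`, `shape`, `layer`,
#'   `checksums`).
#' @export
write_expression <- function(x, dir, basename = "expression",
                             format = c("mtx", "csv")) {
  stopifnot(inherits(x, "expr_matrix"))
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (format == "csv") {
    path <- file.path(dir, paste0(basename, ".csv"))
    df <- tibble::as_tibble(as.matrix(expr_values(x)))
    df <- dplyr::bind_cols(tibble::tibble(cell_id = expr_cells(x)), df)
    readr::write_csv(df, path, progress = FALSE)
    paths <- c(matrix = path)
  } else {
    mp <- file.path(dir, paste0(basename, ".mtx"))
    cp <- file.path(dir, paste0(basename, "_cells.tsv"))
    gp <- file.path(dir, paste0(basename, "_genes.tsv"))
    Matrix::writeMM(expr_values(x), mp)
    writeLines(expr_cells(x), cp)
    writeLines(expr_genes(x), gp)
    paths <- c(matrix = mp, cells = cp, genes = gp)
  }
  manifest <- list(paths = as.list(paths), shape = dim(x),
                   layer = expr_layer(x),
                   checksums = as.list(tools::md5sum(unname(paths))))
  invisible(manifest)
}

#' Read / write the per-cell annotation table
#'
#' Tab-separated with header `cell_id  reference_label  group`; one row per
#' cell.
#'
#' @param path File path.
#' @return A tibble with columns `cell_id`, `reference_label`, `group`.
#' @export
read_cell_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  need <- c("cell_id", "reference_label", "group")
  if (!all(need %in% names(df))) {
    stop(sprintf("cell table must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  df <- df[, need]
  if (anyDuplicated(df$cell_id)) {
    stop("cell table has duplicated cell_id rows", call. = FALSE)
  }
  df
}

#' @rdname read_cell_table
#' @param cells A cell-table tibble.
#' @export
write_cell_table <- function(cells, path) {
  readr::write_tsv(cells[, c("cell_id", "reference_label", "group")], path,
                   progress = FALSE)
  invisible(path)
}

#' Read a per-cell probability table from CSV
#'
#' Header = class labels, first column = cell ids, numeric body. This is the
#' ingestion path for probabilities produced by an external annotator. Rows
#' whose sum is within 1e-3 of 1 are renormalised; larger deviations, or any
#' entry outside \[0, 1\], are fatal.
#'
#' @param path CSV path.
#' @return A [prob_matrix()].
#' @export
read_probability_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(vapply(df[-1], is.numeric, logical(1)))) {
    stop("probability table body must be numeric", call. = FALSE)
  }
  prob_matrix(df, renorm_tol = 1e-3)
}

#' @rdname read_probability_table
#' @param p A `prob_matrix`.
#' @export
write_probability_table <- function(p, path) {
  readr::write_csv(tibble::as_tibble(p), path, progress = FALSE)
  invisible(path)
}
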