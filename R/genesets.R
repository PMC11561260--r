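#' Read gene sets from a GMT file
#'
#' One set per line: `name TAB description TAB gene1 TAB gene2 ...`. The
#' description may be empty, and member genes may be separated by tabs or
#' mixed whitespace. Duplicate genes within a set are removed (first
#' occurrence kept); sets with an empty member list are rejected with a
#' warning; a duplicated set name is fatal.
#'
#' @param path Path to a GMT file.
#' @param quiet Suppress the per-set size report.
#' @return A `gene_set_collection`: a named list of character gene vectors
#'   with a `description` attribute.
#' @export
read_gene_sets <- function(path, quiet = TRUE) {
  if (!file.exists(path)) stop(sprintf("GMT file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character()
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2) {
      stop(sprintf("malformed GMT line (need at least name and description): %s",
                   substr(ln, 1, 60)), call. = FALSE)
    }
    name <- fields[1]
    members <- unlist(strsplit(fields[-(1:2)], "[ \t]+"))
    members <- unique(members[nzchar(members)])
    if (name %in% names(sets)) {
      stop(sprintf("duplicate gene set name: %s", name), call. = FALSE)
    }
    if (length(members) == 0) {
      warning(sprintf("gene set '%s' has no genes and was rejected", name),
              call. = FALSE)
      next
    }
    sets[[name]] <- members
    desc[name] <- fields[2]
    if (!quiet) message(sprintf("  %s: %d genes", name, length(members)))
  }
  gene_set_collection(sets, desc)
}

#' Build a gene-set collection in memory
#'
#' @param sets Named list of character gene vectors (duplicates within a set
#'   removed).
#' @param description Optional named character vector of descriptions.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)) ||
      any(!nzchar(names(sets)))) {
    stop("gene sets must have unique non-empty names", call. = FALSE)
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0)) stop("gene sets must be non-empty", call. = FALSE)
  if (is.null(description)) {
    description <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(sets, description = description[names(sets)],
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets\n", length(x)))
  n <- utils::head(names(x), 10)
  for (nm in n) cat(sprintf("  %s (%d genes)\n", nm, length(x[[nm]])))
  if (length(x) > 10) cat(sprintf("  ... and %d more\n", length(x) - 10))
  invisible(x)
}

#' Write a gene-set collection to GMT
#'
#' @param gsc A `gene_set_collection`.
#' @param path Output path.
#' @export
write_gene_sets <- function(gsc, path) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  desc <- attr(gsc, "description")
  lines <- vapply(names(gsc), function(nm) {
    paste(c(nm, desc[[nm]] %||% "", gsc[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
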