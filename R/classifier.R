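#' Library-size normalise and log-transform raw counts
#'
#' Scales each cell to a fixed target library size and applies `log1p`; the
#' shared normalisation recipe for classifier training and prediction.
#' Cells with zero total counts carry no information and are dropped with a
#' warning.
#'
#' @param x An `expr_matrix` with layer `raw_counts`.
#' @param target_size Target library size per cell.
#' @return An `expr_matrix` with layer `lognorm`.
#' @export
normalize_counts <- function(x, target_size = 1e4) {
  stopifnot(inherits(x, "expr_matrix"))
  if (expr_layer(x) != "raw_counts") {
    stop("input is already normalized (layer is not 'raw_counts')",
         call. = FALSE)
  }
  v <- expr_values(x)
  totals <- Matrix::rowSums(v)
  zero <- totals == 0
  if (any(zero)) {
    warning(sprintf("dropping %d all-zero cell(s)", sum(zero)), call. = FALSE)
    v <- v[!zero, , drop = FALSE]
    totals <- totals[!zero]
  }
  if (nrow(v) == 0) stop("no cells left after dropping all-zero cells", call. = FALSE)
  dn <- dimnames(v)
  v <- Matrix::Diagonal(x = target_size / totals) %*% v
  v <- methods::as(v, "CsparseMatrix")
  v@x <- log1p(v@x)
  dimnames(v) <- dn
  expression_matrix(v, layer = "lognorm")
}

# Feature construction shared by fit and predict. spec is either
# list(kind = "gene_sets", sets = <named list of gene vectors>) or
# list(kind = "genes", genes = <character>). Genes absent from the matrix
# contribute zero.
build_features <- function(lognorm, spec, warn_coverage = FALSE) {
  v <- expr_values(lognorm)
  if (spec$kind == "gene_sets") {
    model_genes <- unique(unlist(spec$sets))
  } else {
    model_genes <- spec$genes
  }
  present <- intersect(model_genes, colnames(v))
  if (length(present) == 0) {
    stop("no overlap between model genes and query genes", call. = FALSE)
  }
  if (warn_coverage && length(present) < 0.8 * length(model_genes)) {
    warning(sprintf("query is missing %d of %d model genes (> 20%%)",
                    length(model_genes) - length(present), length(model_genes)),
            call. = FALSE)
  }
  if (spec$kind == "genes") {
    f <- matrix(0, nrow = nrow(v), ncol = length(spec$genes),
                dimnames = list(rownames(v), spec$genes))
    f[, present] <- as.matrix(v[, present, drop = FALSE])
    return(f)
  }
  f <- vapply(names(spec$sets), function(nm) {
    g <- intersect(spec$sets[[nm]], colnames(v))
    if (length(g) == 0) return(numeric(nrow(v)))
    # mean over the full set size so absent genes count as zero expression
    Matrix::rowSums(v[, g, drop = FALSE]) / length(spec$sets[[nm]])
  }, numeric(nrow(v)))
  rownames(f) <- rownames(v)
  f
}

#' Train a probabilistic cell-type classifier on a reference
#'
#' Fits the default backend: gene-set score features (mean log-normalised
#' expression per set, mirroring pathway-masked annotators; top-variance
#' genes when no gene sets are given) feeding an L2-regularised multinomial
#' linear model (glmnet, `alpha = 0`) with probability output. The
#' regularisation strength is fixed and deliberately strong so that
#' predicted probabilities vary smoothly along a commitment continuum
#' rather than saturating at 0/1 — the property that makes window-based
#' hybrid counting meaningful. Any external annotator's probabilities can
#' stand in for this stage via [read_probability_table()].
#'
#' @param ref An `expr_matrix` (raw counts are normalised internally).
#' @param cells Cell table with `cell_id` and `reference_label` covering the
#'   training cells; every labelled cell must be present in `ref`.
#' @param gene_sets Optional [gene_set_collection()] defining the feature
#'   scores; when `NULL`, the top `n_top_genes` most variable genes are used
#'   directly as features.
#' @param hyperparams Optional overrides: `lambda` (ridge penalty, default
#'   0.075), `n_top_genes` (default 200), `target_size` (normalisation,
#'   default 1e4), `holdout` (diagnostic split fraction, default 0.2),
#'   `balanced` (balanced class weights, default TRUE),
#'   `case_insensitive` (gene symbol matching fallback, default FALSE).
#' @param seed Seed controlling the diagnostic split.
#' @return A `plasticity_classifier` with the fitted model, feature spec,
#'   class vocabulary, normalisation recipe and a training log (class
#'   counts, held-out accuracy, seed, hyperparameters).
#' @export
fit_classifier <- function(ref, cells, gene_sets = NULL,
                           hyperparams = list(), seed = 1L) {
  stopifnot(inherits(ref, "expr_matrix"))
  hp <- utils::modifyList(list(lambda = 0.075, n_top_genes = 200,
                               target_size = 1e4, holdout = 0.2,
                               balanced = TRUE, case_insensitive = FALSE),
                          hyperparams)
  missing_cells <- setdiff(cells$cell_id, expr_cells(ref))
  if (length(missing_cells) > 0) {
    stop(sprintf("%d labelled cell(s) absent from the expression matrix",
                 length(missing_cells)), call. = FALSE)
  }
  classes <- sort(unique(cells$reference_label))
  if (length(classes) < 2) {
    stop("reference must contain at least 2 classes", call. = FALSE)
  }
  if (nrow(cells) < 1000) {
    warning(sprintf(
      "reference has %d cells; >= 1,000 is recommended for stable training",
      nrow(cells)), call. = FALSE)
  }
  lognorm <- if (expr_layer(ref) == "raw_counts") {
    normalize_counts(ref, hp$target_size)
  } else ref
  keep <- intersect(cells$cell_id, expr_cells(lognorm))
  lognorm <- expr_subset(lognorm, cells = keep)
  labels <- cells$reference_label[match(keep, cells$cell_id)]

  if (!is.null(gene_sets)) {
    stopifnot(inherits(gene_sets, "gene_set_collection"))
    genes <- expr_genes(lognorm)
    match_set <- function(g) {
      hit <- intersect(g, genes)
      if (length(hit) == 0 && hp$case_insensitive) {
        hit <- genes[match(tolower(g), tolower(genes), nomatch = 0)]
      }
      hit
    }
    matched <- lapply(gene_sets, match_set)
    empty <- lengths(matched) == 0
    if (all(empty)) {
      stop("gene sets match zero genes in the expression matrix", call. = FALSE)
    }
    if (any(empty)) {
      warning(sprintf("dropping %d gene set(s) with no matching genes: %s",
                      sum(empty), paste(names(matched)[empty], collapse = ", ")),
              call. = FALSE)
    }
    spec <- list(kind = "gene_sets", sets = matched[!empty])
  } else {
    vars <- col_variances(expr_values(lognorm))
    n_top <- min(hp$n_top_genes, ncol(lognorm))
    spec <- list(kind = "genes",
                 genes = expr_genes(lognorm)[order(vars, decreasing = TRUE)[seq_len(n_top)]])
  }
  feats <- build_features(lognorm, spec)
  if (ncol(feats) < 2) {
    # glmnet needs at least two predictors; pad with a zero column
    feats <- cbind(feats, .pad = 0)
  }

  fit_glmnet <- function(x, y) {
    # balanced class weights keep the probability scale centred when the
    # reference atlas is imbalanced (glmnet rescales weights to sum to n)
    w <- if (isTRUE(hp$balanced)) as.numeric(1 / table(y)[y]) else rep(1, length(y))
    glmnet::glmnet(x, factor(y, levels = classes), family = "multinomial",
                   alpha = 0, weights = w,
                   lambda = hp$lambda * c(16, 8, 4, 2, 1),
                   standardize = FALSE)
  }
  # diagnostic stratified split, then the final fit on all cells
  holdout_acc <- NA_real_
  if (hp$holdout > 0 && length(keep) >= 10 * length(classes)) {
    idx_test <- withr::with_seed(seed, {
      unlist(lapply(split(seq_along(labels), labels), function(ix)
        sample(ix, max(1, round(hp$holdout * length(ix))))))
    })
    fit_d <- fit_glmnet(feats[-idx_test, , drop = FALSE], labels[-idx_test])
    pr <- predict(fit_d, feats[idx_test, , drop = FALSE],
                  s = hp$lambda, type = "response")[, , 1]
    pred <- classes[max.col(pr, ties.method = "first")]
    holdout_acc <- mean(pred == labels[idx_test])
  }
  fit <- fit_glmnet(feats, labels)
  structure(list(
    backend = "glmnet_multinomial",
    fit = fit,
    feature_spec = spec,
    classes = classes,
    norm = list(target_size = hp$target_size),
    hyperparams = hp,
    seed = as.integer(seed),
    training_log = list(
      n_cells = length(keep),
      class_counts = as.list(table(labels)),
      holdout_accuracy = holdout_acc,
      holdout_fraction = hp$holdout,
      lambda = hp$lambda,
      seed = as.integer(seed)
    )
  ), class = "plasticity_classifier")
}

col_variances <- function(v) {
  n <- nrow(v)
  mu <- Matrix::colMeans(v)
  (Matrix::colSums(v^2) - n * mu^2) / (n - 1)
}

#' @export
print.plasticity_classifier <- function(x, ...) {
  cat(sprintf("<plasticity_classifier> %d classes (%s), %s features (%d), lambda = %g\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              x$feature_spec$kind,
              if (x$feature_spec$kind == "gene_sets") length(x$feature_spec$sets)
              else length(x$feature_spec$genes),
              x$hyperparams$lambda))
  if (!is.na(x$training_log$holdout_accuracy)) {
    cat(sprintf("  held-out accuracy: %.3f (%d cells)\n",
                x$training_log$holdout_accuracy, x$training_log$n_cells))
  }
  invisible(x)
}

#' Predict per-cell class probabilities
#'
#' Applies the model's normalisation recipe when the query is raw counts,
#' rebuilds the feature scores (genes absent from the query are treated as
#' zero, with a warning when more than 20% of model genes are missing) and
#' returns the probability simplex per cell.
#'
#' @param model A `plasticity_classifier`.
#' @param query An `expr_matrix`.
#' @return A [prob_matrix()] over the model's class vocabulary.
#' @export
predict_proba <- function(model, query) {
  stopifnot(inherits(model, "plasticity_classifier"),
            inherits(query, "expr_matrix"))
  lognorm <- if (expr_layer(query) == "raw_counts") {
    normalize_counts(query, model$norm$target_size)
  } else query
  feats <- build_features(lognorm, model$feature_spec, warn_coverage = TRUE)
  # align feature columns with the fitted predictors (covers the zero-pad
  # column added when only one feature exists)
  want <- rownames(model$fit$beta[[1]])
  miss <- setdiff(want, colnames(feats))
  if (length(miss) > 0) {
    feats <- cbind(feats, matrix(0, nrow(feats), length(miss),
                                 dimnames = list(NULL, miss)))
  }
  feats <- feats[, want, drop = FALSE]
  pr <- predict(model$fit, feats, s = model$hyperparams$lambda,
                type = "response")[, , 1, drop = FALSE]
  pr <- matrix(pr, nrow = nrow(feats),
               dimnames = list(rownames(feats), model$classes))
  prob_matrix(pr, renorm_tol = 1e-3)
}

#' Hard label assignment from a probability matrix
#'
#' Argmax per row; ties broken by the first label in vocabulary order.
#'
#' @param p A `prob_matrix`.
#' @return A tibble with `cell_id` and `predicted_label`.
#' @export
assign_labels <- function(p) {
  stopifnot(inherits(p, "prob_matrix"))
  m <- prob_values(p)
  tibble::tibble(cell_id = p$cell_id,
                 predicted_label = prob_classes(p)[max.col(m, ties.method = "first")])
}

#' Save / load a trained classifier
#'
#' The model is a single serialisable archive; reloading yields bitwise
#' identical predictions.
#'
#' @param model A `plasticity_classifier`.
#' @param path File path (`.rds`).
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "plasticity_classifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("model file not found: %s", path), call. = FALSE)
  }
  model <- readRDS(path)
  if (!inherits(model, "plasticity_classifier")) {
    stop("file does not contain a plasticity_classifier", call. = FALSE)
  }
  model
}
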