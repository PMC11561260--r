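#' Branching differentiation topology
#'
#' A directed tree of cell types. Each edge carries a pseudotime span of
#' \[0, 1\] from parent to child. The default emulates a lineage-negative
#' bone-marrow caricature: an HSC-like root branching into GMP-like and
#' MEP-like intermediates that mature into neutrophil- and mast-cell
#' progenitor endpoints.
#'
#' @param edges A data frame with columns `parent` and `child`.
#' @return A `branch_topology`: the edges tibble with attributes `nodes` and
#'   `root`.
#' @export
branch_topology <- function(edges) {
  edges <- tibble::as_tibble(edges)[, c("parent", "child")]
  edges$parent <- as.character(edges$parent)
  edges$child <- as.character(edges$child)
  nodes <- unique(c(edges$parent, edges$child))
  if (anyDuplicated(edges$child)) {
    stop("topology is not a tree: a node has two parents", call. = FALSE)
  }
  roots <- setdiff(edges$parent, edges$child)
  if (length(roots) != 1) {
    stop(sprintf("topology must have exactly one root (found %d)",
                 length(roots)), call. = FALSE)
  }
  # reachability from root doubles as the acyclicity check for a tree
  seen <- roots
  repeat {
    nxt <- unique(edges$child[edges$parent %in% seen])
    if (all(nxt %in% seen)) break
    seen <- union(seen, nxt)
  }
  if (!setequal(seen, nodes)) {
    stop("every cell type must be reachable from the root", call. = FALSE)
  }
  structure(edges, nodes = nodes, root = roots,
            class = c("branch_topology", class(edges)))
}

#' @rdname branch_topology
#' @export
default_topology <- function() {
  branch_topology(tibble::tibble(
    parent = c("HSC", "HSC", "GMP", "MEP"),
    child = c("GMP", "MEP", "Pro_NE", "Pro_Mast")
  ))
}

#' Simulation configuration
#'
#' Defaults describe a realistic small scRNA-seq experiment on a
#' differentiation continuum: 2,000 cells, 320 genes of which each of the
#' five cell-type programs owns 50, a 2.5 log2-fold program step, moderate
#' negative-binomial overdispersion (UMI-like dispersion 0.2) and lognormal
#' library sizes around 5,000 counts.
#'
#' @param n_cells Number of cells.
#' @param n_genes Number of genes (must cover all programs).
#' @param genes_per_program Genes owned by each cell-type program.
#' @param program_effect_size Program step height, in log2 fold change over
#'   baseline when a program is fully active.
#' @param nb_dispersion Negative-binomial dispersion (1/size); 0 is Poisson.
#' @param library_size_mean Median cell library size; sizes are lognormal
#'   with `library_size_sdlog` spread on the log scale.
#' @param library_size_sdlog Lognormal sdlog of library sizes.
#' @param hybrid_fraction_target Fraction of each edge's cells planted with
#'   a fate-mixture weight uniform in \[0.4, 0.6\] (truth-hybrid cells).
#' @param activation_steepness Slope of the sigmoid converting fate-mixture
#'   weight into program activation.
#' @param seed Integer seed; the whole simulation is reproducible under it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cells = 2000, n_genes = 320, genes_per_program = 50,
                       program_effect_size = 2.5, nb_dispersion = 0.2,
                       library_size_mean = 5000, library_size_sdlog = 0.3,
                       hybrid_fraction_target = 0.1,
                       activation_steepness = 4, seed = 1L) {
  cfg <- list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
              genes_per_program = as.integer(genes_per_program),
              program_effect_size = program_effect_size,
              nb_dispersion = nb_dispersion,
              library_size_mean = library_size_mean,
              library_size_sdlog = library_size_sdlog,
              hybrid_fraction_target = hybrid_fraction_target,
              activation_steepness = activation_steepness,
              seed = as.integer(seed))
  stopifnot(cfg$n_cells > 0, cfg$n_genes > 0, cfg$genes_per_program > 0,
            cfg$nb_dispersion >= 0, cfg$library_size_mean > 0,
            cfg$program_effect_size >= 0)
  if (cfg$hybrid_fraction_target < 0 || cfg$hybrid_fraction_target > 1) {
    stop("hybrid_fraction_target must be in [0, 1]", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a branching differentiation continuum with known fate mixtures
#'
#' Each cell type owns a gene program. A cell sits on one edge of the
#' topology with a fate-mixture weight `w` for the downstream (child) type;
#' its mean expression blends the two flanking programs through a sigmoid
#' activation of `w`, counts are drawn negative-binomial with lognormal
#' library sizes. A fraction `hybrid_fraction_target` of each edge's cells
#' receives `w` uniform in \[0.4, 0.6\] (truth-hybrid); the remainder draw
#' `w` uniformly outside that window. The reference label is the child type
#' when `w >= 0.5`, else the parent type.
#'
#' @param topology A [branch_topology()].
#' @param config A [sim_config()].
#' @return A `branch_sim` list: `expression` (raw counts [expression_matrix()]),
#'   `cells` (cell table tibble), `truth` (tibble with `cell_id`, `parent`,
#'   `child`, `edge`, `true_type`, `pseudotime`, `w_child`, `is_hybrid`),
#'   `programs` (a [gene_set_collection()] of the type programs), plus the
#'   inputs.
#' @export
simulate_branching <- function(topology = default_topology(),
                               config = sim_config()) {
  stopifnot(inherits(topology, "branch_topology"),
            inherits(config, "sim_config"))
  nodes <- attr(topology, "nodes")
  n_prog_genes <- length(nodes) * config$genes_per_program
  if (config$n_genes < n_prog_genes) {
    stop(sprintf("n_genes (%d) is smaller than the %d program genes required",
                 config$n_genes, n_prog_genes), call. = FALSE)
  }
  withr::with_seed(config$seed, {
    gene_ids <- c(
      unlist(lapply(nodes, function(nd)
        sprintf("%s_prog_%03d", nd, seq_len(config$genes_per_program)))),
      sprintf("BG_%03d", seq_len(config$n_genes - n_prog_genes))
    )
    programs <- stats::setNames(lapply(nodes, function(nd)
      sprintf("%s_prog_%03d", nd, seq_len(config$genes_per_program))), nodes)

    n_edges <- nrow(topology)
    edge_idx <- rep(seq_len(n_edges), length.out = config$n_cells)
    is_hybrid <- stats::runif(config$n_cells) < config$hybrid_fraction_target
    w <- numeric(config$n_cells)
    w[is_hybrid] <- stats::runif(sum(is_hybrid), 0.4, 0.6)
    u <- stats::runif(sum(!is_hybrid), 0, 0.8)
    w[!is_hybrid] <- ifelse(u < 0.4, u, u + 0.2)

    parent <- topology$parent[edge_idx]
    child <- topology$child[edge_idx]
    act <- stats::plogis(config$activation_steepness * (w - 0.5))

    # per-cell relative means: baseline 1, programs stepped up by the blend
    prog_col <- stats::setNames(lapply(nodes, function(nd)
      match(programs[[nd]], gene_ids)), nodes)
    rel <- matrix(1, nrow = config$n_cells, ncol = config$n_genes)
    for (nd in nodes) {
      a <- numeric(config$n_cells)          # activation of nd's program
      a[child == nd] <- act[child == nd]
      a[parent == nd] <- 1 - act[parent == nd]
      rel[, prog_col[[nd]]] <- 2^(config$program_effect_size * a)
    }
    lib <- stats::rlnorm(config$n_cells, log(config$library_size_mean),
                         config$library_size_sdlog)
    mu <- rel / rowSums(rel) * lib
    counts <- if (config$nb_dispersion > 0) {
      matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                            size = 1 / config$nb_dispersion),
             nrow = config$n_cells)
    } else {
      matrix(stats::rpois(length(mu), as.vector(mu)), nrow = config$n_cells)
    }
    cell_ids <- sprintf("cell_%05d", seq_len(config$n_cells))
    dimnames(counts) <- list(cell_ids, gene_ids)

    truth <- tibble::tibble(
      cell_id = cell_ids, parent = parent, child = child,
      edge = paste0(parent, "->", child),
      true_type = ifelse(w >= 0.5, child, parent),
      pseudotime = w, w_child = w, is_hybrid = is_hybrid
    )
    cells <- tibble::tibble(cell_id = cell_ids,
                            reference_label = truth$true_type,
                            group = "sim")
    structure(list(
      expression = expression_matrix(counts, layer = "raw_counts"),
      cells = cells, truth = truth,
      programs = gene_set_collection(programs),
      topology = topology, config = config
    ), class = "branch_sim")
  })
}

#' Ground-truth hybrid fraction on one edge
#'
#' The fraction of an edge's cells whose fate-mixture weight lies in the
#' closed window — the ground-truth analogue of the hybrid-cell proportion,
#' used in recovery tests.
#'
#' @param truth The `truth` tibble from [simulate_branching()].
#' @param edge Either an `"A->B"` string or a length-2 character vector
#'   `c(parent, child)`.
#' @param window Closed interval, default `c(0.4, 0.6)`.
#' @return A single proportion.
#' @export
truth_hybrid_fraction <- function(truth, edge, window = c(0.4, 0.6)) {
  if (length(edge) == 2) edge <- paste0(edge[1], "->", edge[2])
  w <- truth$w_child[truth$edge == edge]
  if (length(w) == 0) {
    stop(sprintf("no cells on edge '%s'", edge), call. = FALSE)
  }
  mean(w >= window[1] & w <= window[2])
}

#' Write a simulated dataset as an on-disk fixture
#'
#' Writes the expression matrix (Matrix Market triplet), cell table, truth
#' table and the program gene sets (GMT), plus a JSON manifest recording the
#' configuration, seed, paths, shapes and checksums.
#'
#' @param sim A `branch_sim`.
#' @param dir Output directory.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return Invisibly, the manifest list.
#' @export
write_fixture <- function(sim, dir, overwrite = FALSE) {
  stopifnot(inherits(sim, "branch_sim"))
  if (dir.exists(dir) && length(dir(dir)) > 0 && !overwrite) {
    stop(sprintf("directory '%s' is not empty (use overwrite = TRUE)", dir),
         call. = FALSE)
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  expr_manifest <- write_expression(sim$expression, dir, "expression")
  cells_path <- file.path(dir, "cells.tsv")
  truth_path <- file.path(dir, "truth.tsv")
  gmt_path <- file.path(dir, "programs.gmt")
  write_cell_table(sim$cells, cells_path)
  readr::write_tsv(sim$truth, truth_path, progress = FALSE)
  write_gene_sets(sim$programs, gmt_path)
  extra <- c(cells = cells_path, truth = truth_path, programs = gmt_path)
  manifest <- list(
    config = unclass(sim$config),
    seed = sim$config$seed,
    topology = as.data.frame(sim$topology),
    expression = expr_manifest,
    paths = as.list(extra),
    checksums = as.list(tools::md5sum(unname(extra)))
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
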