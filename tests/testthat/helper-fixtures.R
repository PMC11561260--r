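# Shared fixtures, memoised so repeated tests reuse one simulation/fit.
.fix_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fix_cache)) {
    assign(key, force(expr), envir = .fix_cache)
  }
  get(key, envir = .fix_cache)
}

# standard study-condition simulation
fix_sim <- function(f = 0.1, seed = 1, n_cells = 2000, ...) {
  key <- paste0("sim_", f, "_", seed, "_", n_cells, "_",
                paste(c(...), collapse = "_"))
  cached(key, simulate_branching(config = sim_config(
    hybrid_fraction_target = f, seed = seed, n_cells = n_cells, ...)))
}

# sharply committed, well-separated population (no planted hybrids)
fix_sim_separated <- function(seed = 1, n_cells = 2000) {
  fix_sim(f = 0, seed = seed, n_cells = n_cells,
          program_effect_size = 6, activation_steepness = 8)
}

fix_model <- function(sim, seed = 1, ...) {
  key <- paste0("model_", substr(digest_sim(sim), 1, 12), "_", seed, "_",
                paste(c(...), collapse = "_"))
  cached(key, suppressWarnings(fit_classifier(
    sim$expression, sim$cells, gene_sets = sim$programs,
    hyperparams = list(holdout = 0, ...), seed = seed)))
}

fix_probs <- function(sim, model = fix_model(sim)) {
  key <- paste0("probs_", substr(digest_sim(sim), 1, 12))
  cached(key, predict_proba(model, sim$expression))
}

digest_sim <- function(sim) {
  paste0(sim$config$seed, "_", sim$config$n_cells, "_",
         sim$config$hybrid_fraction_target, "_",
         sim$config$program_effect_size)
}

# random probability simplex matrix (independent of package internals)
random_probs <- function(n, k, seed) {
  withr::with_seed(seed, {
    m <- matrix(rgamma(n * k, shape = 1), n, k)
    m <- m / rowSums(m)
    dimnames(m) <- list(sprintf("c%04d", seq_len(n)), LETTERS[seq_len(k)])
    m
  })
}

# brute-force oracles: plain loops, no vectorised shortcuts
oracle_bias <- function(pa, pb) {
  out <- numeric(length(pa))
  for (i in seq_along(pa)) out[i] <- pa[i] / (pa[i] + pb[i])
  out
}

oracle_window_count <- function(bias, lo, hi) {
  n <- 0
  for (b in bias) if (b >= lo && b <= hi) n <- n + 1
  n
}

# pipeline phc averaged over the topology's edges (eligibility = edge cells)
pipeline_edge_phc <- function(sim, probs, window = c(0.4, 0.6)) {
  vapply(seq_len(nrow(sim$topology)), function(i) {
    pa <- sim$topology$parent[i]
    ch <- sim$topology$child[i]
    ids <- sim$truth$cell_id[sim$truth$edge == paste0(pa, "->", ch)]
    phc(fate_bias(probs, pa, ch, eligible = ids), window)
  }, numeric(1))
}

# tiny handmade probability matrix over classes A, B, C
probe_probs <- function(rows) {
  m <- do.call(rbind, rows)
  colnames(m) <- c("A", "B", "C")
  rownames(m) <- sprintf("cell%d", seq_len(nrow(m)))
  prob_matrix(m)
}
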