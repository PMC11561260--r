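test_that("normalisation scales to target library size and guards the layer", {
  m <- matrix(c(10, 10, 0, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("c1", "c2"), c("g1", "g2")))
  x <- expression_matrix(m)
  expect_warning(n <- normalize_counts(x, target_size = 20), "all-zero")
  expect_equal(nrow(n), 1L)
  expect_equal(as.numeric(expr_values(n)["c1", ]), rep(log1p(10), 2))
  expect_identical(expr_layer(n), "lognorm")
  expect_error(normalize_counts(n), "already normalized")
})

test_that("training rejects degenerate references", {
  sim <- fix_sim(f = 0.1, seed = 1, n_cells = 300)
  one_class <- dplyr::mutate(sim$cells, reference_label = "X")
  expect_error(suppressWarnings(
    fit_classifier(sim$expression, one_class)), "at least 2 classes")
  bogus <- gene_set_collection(list(S = c("not_a_gene_1", "not_a_gene_2")))
  expect_error(suppressWarnings(
    fit_classifier(sim$expression, sim$cells, gene_sets = bogus)),
    "zero genes")
  expect_warning(fit_classifier(sim$expression, sim$cells,
                                gene_sets = sim$programs),
                 "1,000")
})

test_that("well-separated classes are learned almost perfectly", {
  sim <- fix_sim_separated(seed = 11)
  model <- suppressWarnings(fit_classifier(sim$expression, sim$cells,
                                           gene_sets = sim$programs, seed = 3))
  expect_gt(model$training_log$holdout_accuracy, 0.95)
  # top-variance fallback (no gene sets) reaches the same regime
  model2 <- suppressWarnings(fit_classifier(sim$expression, sim$cells,
                                            seed = 3))
  expect_identical(model2$feature_spec$kind, "genes")
  expect_gt(model2$training_log$holdout_accuracy, 0.95)
})

test_that("predicted probabilities live on the simplex and are deterministic", {
  sim <- fix_sim(f = 0.1, seed = 1)
  probs <- fix_probs(sim)
  pv <- prob_values(probs)
  expect_true(all(abs(rowSums(pv) - 1) < 1e-6))
  expect_true(all(pv >= 0 & pv <= 1))
  # a duplicated single-cell query yields identical rows
  one <- expr_subset(sim$expression, cells = expr_cells(sim$expression)[1])
  trip <- expression_matrix(
    as.matrix(expr_values(one))[rep(1, 3), , drop = FALSE],
    cell_ids = c("d1", "d2", "d3"), gene_ids = expr_genes(one))
  p3 <- prob_values(predict_proba(fix_model(sim), trip))
  expect_equal(p3[1, ], p3[2, ])
  expect_equal(p3[1, ], p3[3, ])
})

test_that("training is reproducible and models serialize losslessly", {
  sim <- fix_sim(f = 0.1, seed = 1, n_cells = 1200)
  m1 <- suppressWarnings(fit_classifier(sim$expression, sim$cells,
                                        gene_sets = sim$programs, seed = 9))
  m2 <- suppressWarnings(fit_classifier(sim$expression, sim$cells,
                                        gene_sets = sim$programs, seed = 9))
  expect_identical(serialize(m1, NULL), serialize(m2, NULL))
  p <- withr::local_tempfile(fileext = ".rds")
  save_classifier(m1, p)
  m3 <- load_classifier(p)
  expect_identical(prob_values(predict_proba(m1, sim$expression)),
                   prob_values(predict_proba(m3, sim$expression)))
})

test_that("gene order in the query does not affect predictions", {
  sim <- fix_sim(f = 0.1, seed = 1, n_cells = 600)
  model <- fix_model(sim)
  base <- prob_values(predict_proba(model, sim$expression))
  perm <- withr::with_seed(4, sample(ncol(sim$expression)))
  shuffled <- expression_matrix(expr_values(sim$expression)[, perm],
                                layer = "raw_counts")
  expect_equal(prob_values(predict_proba(model, shuffled)), base,
               tolerance = 1e-12)
})

test_that("hard labels use argmax with first-label tie breaking", {
  pm <- probe_probs(list(c(0.7, 0.3, 0), c(0.5, 0.5, 0), c(0.2, 0.3, 0.5)))
  expect_equal(assign_labels(pm)$predicted_label, c("A", "A", "C"))
})

test_that("truth-hybrid cells receive near-equal pair probabilities", {
  sim <- fix_sim(f = 0.1, seed = 5)
  model <- fix_model(sim)
  all_hyb <- simulate_branching(config = sim_config(
    hybrid_fraction_target = 1, n_cells = 2000, seed = 15))
  ids <- all_hyb$truth$cell_id[all_hyb$truth$edge == "GMP->Pro_NE"]
  expect_gte(length(ids), 400)
  probs <- predict_proba(model, all_hyb$expression)
  fb <- fate_bias(probs, "GMP", "Pro_NE", eligible = ids)
  expect_lt(abs(mean(fb$prob_a - fb$prob_b)), 0.15)
})

test_that("confidence deciles have non-decreasing empirical accuracy", {
  sim <- fix_sim(f = 0.1, seed = 21)
  probs <- fix_probs(sim)
  lab <- assign_labels(probs)
  maxp <- apply(prob_values(probs), 1, max)
  ok <- lab$predicted_label == sim$cells$reference_label
  dec <- cut(maxp, stats::quantile(maxp, 0:10 / 10), include.lowest = TRUE)
  acc <- as.numeric(tapply(ok, dec, mean))
  expect_true(all(diff(acc) >= -1e-9))
})
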