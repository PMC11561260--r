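test_that("knockout zeroes exactly the targeted columns", {
  m <- matrix(c(5, 3, 2, 7), nrow = 2,
              dimnames = list(c("c1", "c2"), c("g1", "g2")))
  x <- expression_matrix(m)
  ko <- knockout_gene_set(x, "g1")
  expect_equal(as.matrix(expr_values(ko)),
               matrix(c(0, 0, 2, 7), nrow = 2,
                      dimnames = dimnames(m)))
  expect_identical(attr(ko, "genes_hit"), "g1")
  # idempotent; partial overlap records the missing genes
  ko2 <- knockout_gene_set(ko, c("g1", "g3"))
  expect_equal(as.matrix(expr_values(ko2)), as.matrix(expr_values(ko)))
  expect_identical(attr(ko2, "genes_missing"), "g3")
  expect_error(knockout_gene_set(x, "g3"), "nothing to knock out")
  expect_error(knockout_gene_set(suppressWarnings(normalize_counts(x)), "g1"),
               "raw counts")
})

test_that("no-op knockouts reproduce the baseline bit-exactly", {
  sim <- fix_sim(f = 0.1, seed = 1, n_cells = 600)
  model <- fix_model(sim)
  # query whose first background gene carries zero counts: zeroing it again
  # changes nothing
  v <- expr_values(sim$expression)
  zero_gene <- "BG_001"
  v[, zero_gene] <- 0
  query <- expression_matrix(v, layer = "raw_counts")
  res <- perturb_and_repredict(model, query, zero_gene, set_name = "noop")
  expect_identical(prob_values(res$perturbed_prob),
                   prob_values(res$baseline_prob))
  expect_equal(res$fractions$baseline, res$fractions$perturbed)
})

test_that("perturbation never mutates the trained model", {
  sim <- fix_sim(f = 0.1, seed = 1, n_cells = 600)
  model <- fix_model(sim)
  before <- serialize(model, NULL)
  invisible(perturb_and_repredict(model, sim$expression,
                                  sim$programs[["Pro_NE"]], set_name = "ko"))
  expect_identical(serialize(model, NULL), before)
})

test_that("zeroing an endpoint's program depletes that endpoint", {
  sim <- fix_sim(f = 0.1, seed = 31)
  model <- fix_model(sim)
  res <- perturb_and_repredict(model, sim$expression, sim$programs[["Pro_NE"]],
                               set_name = "Pro_NE_program")
  fr <- res$fractions
  expect_lt(fr$perturbed[fr$class == "Pro_NE"],
            fr$baseline[fr$class == "Pro_NE"])
  expect_lt(mean(res$perturbed_prob$Pro_NE), mean(res$baseline_prob$Pro_NE))
  # fraction columns are distributions over the class vocabulary
  expect_equal(sum(fr$baseline), 1)
  expect_equal(sum(fr$perturbed), 1)
})

test_that("reversal calls follow the between-control-and-disease rule", {
  # published control/disease anchors: 3.22% and 7.25%
  expect_identical(classify_reversal(0.0322, 0.0725, 0.0500),
                   "partially_reversed")
  expect_identical(classify_reversal(0.0322, 0.0725, 0.0900), "not_reversed")
  expect_identical(classify_reversal(0.0322, 0.0725, 0.0200), "reversed")
  # boundary equality is inclusive
  expect_identical(classify_reversal(0.0322, 0.0725, 0.0322),
                   "partially_reversed")
  expect_identical(classify_reversal(0.0322, 0.0725, 0.0725),
                   "partially_reversed")
  # the rule is orientation-free
  expect_identical(classify_reversal(0.0725, 0.0322, 0.0500),
                   "partially_reversed")
  expect_identical(classify_reversal(0.0725, 0.0322, 0.0900), "reversed")
  expect_error(classify_reversal(0.5, 0.2, 1.2), "\\[0, 1\\]")
})

test_that("perturbation reports stack results in long format", {
  sim <- fix_sim(f = 0.1, seed = 31)
  model <- fix_model(sim)
  res <- lapply(c("Pro_NE", "Pro_Mast"), function(nm)
    perturb_and_repredict(model, sim$expression, sim$programs[[nm]],
                          set_name = nm, cells = sim$cells,
                          pairs = list(c("GMP", "Pro_NE"))))
  rep <- perturbation_report(res)
  expect_equal(nrow(rep$fractions), 2 * length(model$classes))
  expect_named(rep$phc, c("gene_set", "pair", "window", "baseline",
                          "perturbed"))
  expect_equal(rep$phc$gene_set, c("Pro_NE", "Pro_Mast"))
})

test_that("ecdf threshold values feed the reversal rule", {
  sim <- fix_sim(f = 0.1, seed = 1)
  probs <- fix_probs(sim)
  ec <- ecdf_curve(probs, "GMP", sim$cells)
  v <- ecdf_value_at(ec, "GMP")
  expect_true(v >= 0 && v <= 1)
  expect_identical(classify_reversal(0, 1, v), "partially_reversed")
  expect_error(ecdf_value_at(ec, "nope"), "no group")
})
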