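test_that("fate bias matches the stated arithmetic on probe cells", {
  pm <- probe_probs(list(c(0.5, 0.5, 0), c(0.9, 0.1, 0), c(0.2, 0.6, 0.2),
                         c(0, 0, 1)))
  fb <- fate_bias(pm, "A", "B")
  # the zero-joint-probability cell is excluded and M decremented
  expect_equal(nrow(fb), 3L)
  expect_identical(attr(fb, "excluded"), "cell4")
  expect_equal(fb$bias, c(0.5, 0.9, 0.25))
  # signed audit form prints the published equation's values
  fs <- fate_bias(pm, "A", "B", method = "signed")
  expect_equal(fs$bias, c(0, 0.8, -0.5))
})

test_that("fate bias validates labels and eligibility", {
  pm <- probe_probs(list(c(0.5, 0.5, 0)))
  expect_error(fate_bias(pm, "A", "Z"), "unknown class")
  expect_error(fate_bias(pm, "A", "A"), "must differ")
  expect_error(fate_bias(pm, "A", "B", eligible = "nope"), "empty")
  pm0 <- probe_probs(list(c(0, 0, 1)))
  expect_error(fate_bias(pm0, "A", "B"), "zero joint probability")
})

test_that("phc counts closed-window membership over the eligible total", {
  pm <- probe_probs(list(c(0.5, 0.5, 0), c(0.5, 0.5, 0), c(0.5, 0.5, 0)))
  expect_equal(phc(fate_bias(pm, "A", "B")), 1)
  pm2 <- probe_probs(list(c(0.1, 0.9, 0), c(0.45, 0.55, 0),
                          c(0.62, 0.38, 0), c(0.95, 0.05, 0)))
  fb2 <- fate_bias(pm2, "A", "B")
  expect_equal(phc(fb2), 0.25)
  expect_equal(phc(fb2, c(0, 1)), 1)
  expect_error(phc(fb2, c(0.6, 0.4)), "window")
  expect_error(phc(fb2, c(-0.1, 0.5)), "window")
})

test_that("fate_bias and phc agree exactly with a brute-force oracle", {
  windows <- list(c(0.35, 0.65), c(0.4, 0.6), c(0.45, 0.55))
  for (s in 1:100) {
    pm <- prob_matrix(random_probs(200, 5, seed = s))
    a <- LETTERS[1 + (s %% 5)]
    b <- LETTERS[1 + ((s + 2) %% 5)]
    fb <- fate_bias(pm, a, b)
    expect_identical(fb$bias, oracle_bias(pm[[a]][pm$cell_id %in% fb$cell_id],
                                          pm[[b]][pm$cell_id %in% fb$cell_id]))
    for (w in windows) {
      expect_identical(phc(fb, w),
                       oracle_window_count(fb$bias, w[1], w[2]) / nrow(fb))
    }
  }
})

test_that("nested windows give monotone non-decreasing phc", {
  for (s in 1:25) {
    pm <- prob_matrix(random_probs(150, 4, seed = 1000 + s))
    fb <- fate_bias(pm, "A", "B")
    expect_lte(phc(fb, c(0.45, 0.55)), phc(fb, c(0.4, 0.6)))
    expect_lte(phc(fb, c(0.4, 0.6)), phc(fb, c(0.35, 0.65)))
  }
})

test_that("bias is symmetric under pair swap and phc invariant for symmetric windows", {
  for (s in 1:20) {
    pm <- prob_matrix(random_probs(100, 5, seed = 2000 + s))
    ab <- fate_bias(pm, "A", "B")
    ba <- fate_bias(pm, "B", "A")
    expect_equal(ab$bias + ba$bias, rep(1, nrow(ab)), tolerance = 1e-12)
    for (w in list(c(0.4, 0.6), c(0.35, 0.65))) {
      expect_equal(phc(ab, w), phc(ba, w))
    }
  }
})

test_that("phc_table mirrors the group x window x pair layout", {
  sim <- fix_sim(f = 0.1, seed = 1)
  probs <- fix_probs(sim)
  tab <- phc_table(probs, sim$cells)
  expect_named(tab, c("group", "window", "HSC vs GMP", "HSC vs MEP",
                      "GMP vs MEP", "GMP vs Pro_NE"))
  expect_equal(nrow(tab), 3L)   # one group, three windows
  # every pair column respects nested-window monotonicity
  for (col in names(tab)[-(1:2)]) {
    v <- tab[[col]]
    expect_lte(v[tab$window == "[0.45, 0.55]"], v[tab$window == "[0.4, 0.6]"])
    expect_lte(v[tab$window == "[0.4, 0.6]"], v[tab$window == "[0.35, 0.65]"])
  }
})

test_that("ecdf curves compute strict threshold fractions per group", {
  pm <- prob_matrix(
    matrix(c(0.2, 0.4, 0.6, 0.8, 1, 1, 1, 1,
             0.8, 0.6, 0.4, 0.2, 0, 0, 0, 0), ncol = 2,
           dimnames = list(paste0("c", 1:8), c("A", "B"))))
  cells <- tibble::tibble(cell_id = paste0("c", 1:8),
                          reference_label = rep(c("g1", "g2"), each = 4),
                          group = "x")
  ec <- ecdf_curve(pm, "A", cells)
  thr <- ec$threshold_fractions
  expect_equal(thr$frac_below[thr$group == "g1"], 0.5)
  expect_equal(thr$frac_below[thr$group == "g2"], 0)    # all probabilities 1
  # cumulative fractions end at 1 and never decrease
  for (g in c("g1", "g2")) {
    fr <- ec$points$frac[ec$points$group == g]
    expect_equal(max(fr), 1)
    expect_true(all(diff(fr) >= 0))
  }
  cells2 <- dplyr::bind_rows(cells,
    tibble::tibble(cell_id = "ghost", reference_label = "g3", group = "x"))
  expect_warning(ecdf_curve(pm, "A", cells2), "g3")
})

test_that("overlap matrix is row-normalised with diagonal flagging", {
  cells <- tibble::tibble(cell_id = paste0("c", 1:3),
                          reference_label = c("A", "A", "B"), group = "x")
  pred <- tibble::tibble(cell_id = paste0("c", 1:3),
                         predicted_label = c("A", "B", "B"))
  om <- overlap_matrix(cells, pred)
  expect_equal(unname(unlist(om[om$reference_label == "A", c("A", "B")])),
               c(0.5, 0.5))
  expect_equal(unname(unlist(om[om$reference_label == "B", c("A", "B")])),
               c(0, 1))
  expect_identical(flagged_types(om), "A")

  ident <- overlap_matrix(cells,
    tibble::tibble(cell_id = cells$cell_id,
                   predicted_label = cells$reference_label))
  expect_length(flagged_types(ident), 0)

  # random assignments always produce rows summing to exactly 1
  for (s in 1:10) {
    n <- 60
    labs <- withr::with_seed(s, list(r = sample(LETTERS[1:4], n, TRUE),
                                     p = sample(LETTERS[1:4], n, TRUE)))
    cells_r <- tibble::tibble(cell_id = paste0("c", 1:n),
                              reference_label = labs$r, group = "x")
    om_r <- overlap_matrix(cells_r,
      tibble::tibble(cell_id = paste0("c", 1:n), predicted_label = labs$p))
    sums <- rowSums(as.matrix(tibble::as_tibble(om_r)[, -1]))
    expect_true(all(abs(sums - 1) < 1e-9))
  }
  expect_error(overlap_matrix(cells,
    tibble::tibble(cell_id = paste0("c", 1:3),
                   predicted_label = c("X", "Y", "X"))), "disjoint")
})

test_that("tidy and glance summarise plasticity results", {
  sim <- fix_sim(f = 0.1, seed = 1)
  probs <- fix_probs(sim)
  fb <- fate_bias(probs, "GMP", "Pro_NE", cells = sim$cells)
  g <- glance(fb)
  expect_equal(g$phc, phc(fb))
  expect_equal(g$n_hybrid / g$m, g$phc)
  td <- tidy(fb)
  expect_true(all(c("cell_id", "bias", "type_a") %in% names(td)))
})
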