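test_that("ROC endpoints behave analytically", {
  # perfect separation passes through (0, 1)
  rc <- roc_curve(c(1, 1, 1), c(0, 0, 0))
  expect_true(any(rc$fpr == 0 & rc$tpr == 1))
  expect_equal(auc_trapezoid(rc), 1)
  expect_equal(auc_rank(c(1, 1, 1), c(0, 0, 0)), 1)
  # indistinguishable groups give the diagonal
  rc2 <- roc_curve(c(3, 3), c(3, 3))
  expect_equal(rc2$fpr, rc2$tpr)
  expect_equal(auc_trapezoid(rc2), 0.5)
  expect_equal(auc_rank(c(3, 3), c(3, 3)), 0.5)
  expect_error(roc_curve(numeric(0), 1), "non-empty")
})

test_that("worked small example matches the pairwise oracle", {
  pos <- c(5, 3, 0)
  neg <- c(2, 0, 0, 1)
  # hand enumeration: 8 wins + 2 ties over 12 pairs -> 0.75
  expect_equal(auc_oracle(pos, neg), 0.75)
  rc <- roc_curve(pos, neg)
  # thresholds: distinct observed values descending plus sentinel
  expect_identical(rc$thresholds, c(5, 3, 2, 1, 0, -1))
  expect_equal(auc_trapezoid(rc), 0.75)
  expect_equal(auc_rank(pos, neg), 0.75)
})

test_that("rank and trapezoid formulas agree on tie-heavy random input", {
  withr::local_seed(7)
  for (i in 1:1000) {
    n_pos <- sample(1:30, 1)
    n_neg <- sample(1:30, 1)
    pos <- sample(0:4, n_pos, replace = TRUE)  # heavy ties, zero-dominated
    neg <- sample(0:4, n_neg, replace = TRUE)
    a_rank <- auc_rank(pos, neg)
    a_trap <- auc_trapezoid(roc_curve(pos, neg))
    expect_equal(a_rank, a_trap, tolerance = 1e-12)
    expect_equal(a_rank, auc_oracle(pos, neg), tolerance = 1e-12)
    # swapping groups reflects the AUC
    expect_equal(auc_rank(neg, pos), 1 - a_rank, tolerance = 1e-12)
    # invariance under a strictly increasing transform
    expect_equal(auc_rank(log1p(pos) * 3, log1p(neg) * 3), a_rank)
  }
})

test_that("AUC table matches per-entry trapezoid oracle on a simulation", {
  sim <- tiny_sim()
  tab <- compute_auc_table(sim$counts, sim$annotation, "type")
  expect_true(all(tab >= 0 & tab <= 1))
  lab <- sim$annotation$type
  m <- as.matrix(sim$counts)
  for (g in sample(colnames(m), 10)) {
    for (ty in colnames(tab)) {
      expect_equal(tab[g, ty],
                   auc_trapezoid(roc_curve(m[lab == ty, g],
                                           m[lab != ty, g])),
                   tolerance = 1e-12)
    }
  }
  # reproducible bit for bit
  expect_identical(tab[, ],
                   compute_auc_table(sim$counts, sim$annotation, "type")[, ])
})

test_that("planted perfect marker and constant genes hit the endpoints", {
  counts <- matrix(0, 40, 2, dimnames = list(sprintf("C%02d", 1:40),
                                             c("MARK", "FLAT")))
  counts[1:10, "MARK"] <- 5
  counts[, "FLAT"] <- 2
  ann <- data.frame(cell_id = rownames(counts),
                    type = rep(c("A", "B", "C", "D"), each = 10))
  tab <- compute_auc_table(expression_matrix(counts), ann, "type")
  expect_equal(tab["MARK", "A"], 1)
  expect_true(all(tab["MARK", c("B", "C", "D")] < 0.5))
  expect_equal(unname(tab["FLAT", ]), rep(0.5, 4))
})

test_that("label permutation centres the AUC at one half", {
  withr::local_seed(11)
  x <- rnbinom(200, size = 1, mu = 2)
  aucs <- replicate(300, {
    idx <- sample(200, 50)
    auc_rank(x[idx], x[-idx])
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.01)
})

test_that("depth normalization changes ranks only through per-cell scale", {
  sim <- tiny_sim()
  raw <- compute_auc_table(sim$counts, sim$annotation, "type")
  norm <- compute_auc_table(sim$counts, sim$annotation, "type",
                            normalize_depth = TRUE)
  expect_true(all(norm >= 0 & norm <= 1))
  # same gene/type layout, values may differ
  expect_identical(dimnames(norm), dimnames(raw))
})

test_that("gene subsetting reports unknown symbols and detection filters", {
  sim <- tiny_sim()
  expect_warning(
    tab <- compute_auc_table(sim$counts, sim$annotation, "type",
                             genes = c("g0001", "NOPE")),
    "skipped")
  expect_identical(rownames(tab), "G0001")

  counts <- expression_matrix(
    cbind(A = c(0, 0, 0), B = c(0, 3, 0), C = c(1, 1, 1)),
    cell_ids = c("C1", "C2", "C3"), gene_ids = c("A", "B", "C"))
  expect_identical(detect_genes(counts), c("B", "C"))
  expect_identical(detect_genes(counts, min_cells = 2), "C")
  expect_identical(detect_genes(counts, min_cells = 5), character(0))
})

test_that("cells with missing labels are dropped from the level", {
  counts <- expression_matrix(matrix(c(1, 2, 3, 4), 4, 1),
                              sprintf("C%d", 1:4), "G1")
  ann <- data.frame(cell_id = sprintf("C%d", 1:4),
                    type = c("A", "B", NA, ""))
  expect_message(tab <- compute_auc_table(counts, ann, "type"), "dropped")
  expect_identical(attr(tab, "n_cells_per_type"), c(A = 1L, B = 1L))
})
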