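test_that("Mann-Whitney worked example matches exhaustive enumeration", {
  res <- compare_sets_mannwhitney(c(0.9, 0.8), c(0.5, 0.6))
  expect_equal(res$u_statistic, 4)
  expect_equal(res$p_two_sided, 1 / 3)
  expect_equal(res$median_diff, 0.30)
  expect_equal(mw_enum_p(c(0.9, 0.8), c(0.5, 0.6)), 1 / 3)
})

test_that("exact p equals enumeration for all tie-free samples up to n = 5", {
  withr::local_seed(3)
  for (i in 1:40) {
    n <- sample(2:5, 1)
    x <- sample(seq(0.01, 0.99, by = 0.01), 2 * n)  # tie-free
    a <- x[seq_len(n)]
    b <- x[-seq_len(n)]
    expect_equal(compare_sets_mannwhitney(a, b)$p_two_sided,
                 mw_enum_p(a, b), tolerance = 1e-12)
  }
})

test_that("identical samples give p = 1 and zero median difference", {
  a <- c(0.7, 0.8, 0.6)
  res <- compare_sets_mannwhitney(a, a)
  expect_equal(res$p_two_sided, 1)
  expect_equal(res$median_diff, 0)
  expect_error(compare_sets_mannwhitney(numeric(0), a), "non-empty")
})

test_that("normal approximation tracks the exact p on tie-free 8x8 samples", {
  withr::local_seed(9)
  for (i in 1:25) {
    x <- sample(seq_len(500), 16) / 500
    a <- x[1:8]
    b <- x[9:16]
    p_exact <- compare_sets_mannwhitney(a, b)$p_two_sided
    p_normal <- compare_sets_mannwhitney(a, b, exact_limit = 0)$p_two_sided
    expect_lt(abs(p_exact - p_normal), 0.02)
  }
})

test_that("a planted shift is detected at large n", {
  withr::local_seed(21)
  a <- runif(200, 0.3, 0.7)
  res <- compare_sets_mannwhitney(a + 0.2, a)
  expect_lt(res$p_two_sided, 0.01)
  expect_gt(res$median_diff, 0.1)
})

test_that("pairwise comparison matrices are symmetric/antisymmetric", {
  withr::local_seed(2)
  sets <- list(base1 = runif(40), base2 = runif(40),
               shifted = runif(40) + 0.5)
  pc <- pairwise_compare(sets)
  expect_equal(pc$p, t(pc$p))
  expect_equal(pc$median_diff, -t(pc$median_diff))
  expect_identical(pc$stars["base1", "shifted"], "**")
  expect_identical(pc$stars["base1", "base2"], "")
  # identical sets: off-diagonal p = 1, no stars
  pc2 <- pairwise_compare(list(x = c(1, 2, 3), y = c(1, 2, 3)))
  expect_equal(pc2$p["x", "y"], 1)
  expect_equal(pc2$median_diff["x", "y"], 0)
  # BH adjustment is monotone in the raw p values
  pcBH <- pairwise_compare(sets, adjust = "BH")
  expect_true(all(pcBH$table$p_adjusted >= pcBH$table$p_two_sided - 1e-12))
  expect_error(pairwise_compare(list(a = 1)), "2")
  expect_error(pairwise_compare(list(a = 1, b = numeric(0))), "empty")
})

test_that("resampling null honours the add-one floor and ceiling", {
  universe <- runif(50)
  # observed below every null draw -> p = 1
  low <- resample_null(rep(-1, 5), universe, B = 99, seed = 1)
  expect_equal(low$p_empirical, 1)
  # observed above every null draw with B = 999 -> p = 1/1000
  high <- resample_null(rep(2, 5), universe, B = 999, seed = 1)
  expect_equal(high$p_empirical, 1 / 1000)
  expect_gt(high$p_empirical, 0)
  # reproducible given the seed
  again <- resample_null(rep(2, 5), universe, B = 999, seed = 1)
  expect_identical(again$null_stats, high$null_stats)
  expect_error(resample_null(1:10, universe, set_size = 100), "universe")
})

test_that("exhaustive resampling matches subset enumeration", {
  universe <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  target <- c(0.7, 0.9)
  res <- resample_null(target, universe, set_size = 2, exhaustive = TRUE)
  expect_identical(res$B, 10L)
  # oracle: medians of all 10 pairs, fraction >= observed median 0.8
  meds <- combn(universe, 2, median)
  expect_equal(res$p_empirical, mean(meds >= 0.8))
})

test_that("constraint summary computes medians and strict fractions", {
  ct <- data.frame(gene = c("A", "B", "C"), loeuf = c(0.3, 0.7, 0.5))
  s <- constraint_summary(c("a", "b", "c"), ct)
  expect_equal(s$median_loeuf, 0.5)
  expect_equal(s$frac_above_threshold, 1 / 3)
  expect_identical(s$n_matched, 3L)
  s2 <- constraint_summary(c("A", "B", "C", "MISSING"), ct)
  expect_identical(s2$n_matched, 3L)
  expect_identical(s2$unmatched, "MISSING")
  s3 <- constraint_summary(c("A"), ct)  # all below threshold
  expect_equal(s3$frac_above_threshold, 0)
  expect_error(constraint_summary("ZZZ", ct), "no gene")
})

test_that("cross-dataset consistency flags shifts, not identity", {
  withr::local_seed(14)
  amax1 <- setNames(runif(30, 0.4, 0.9), paste0("G", 1:30))
  sets <- list(S1 = paste0("G", 1:10), S2 = paste0("G", 11:30))
  same <- cross_dataset_consistency(amax1, amax1, sets)
  expect_equal(same$p_two_sided, c(1, 1))
  shifted <- amax1
  shifted[] <- pmin(amax1 + 0.2, 1.5)
  diff <- cross_dataset_consistency(amax1, shifted, sets)
  expect_true(all(diff$p_two_sided < 0.05))
  expect_error(
    cross_dataset_consistency(amax1, amax1[1:5],
                              list(S = paste0("G", 25:30))),
    "no detected gene")
})
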