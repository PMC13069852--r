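make_tab <- function(m, types = paste0("T", seq_len(ncol(m)))) {
  dimnames(m) <- list(paste0("G", seq_len(nrow(m))), types)
  aucmarker:::new_auc_table(m, level = "type")
}

test_that("auc_max picks the row maximum and breaks ties by table order", {
  tab <- make_tab(rbind(c(0.55, 0.91, 0.60), c(0.70, 0.70, 0.50)))
  expect_message(am <- auc_max(tab), "tied")
  expect_equal(am$auc_max, c(0.91, 0.70))
  expect_identical(am$best_type, c("T2", "T1"))
})

test_that("classification respects the defining threshold inequalities", {
  cls <- classify_genes(c(a = 0.91, b = 0.70, c = 0.55,
                          at_marker = 0.8, at_ubiq = 0.6))
  expect_identical(as.character(cls$category),
                   c("marker", "intermediate", "ubiquitous",
                     "marker",          # 0.8 is a marker (>=)
                     "intermediate"))   # 0.6 is intermediate (<)
  expect_error(classify_genes(0.7, marker_threshold = 0.5,
                              ubiquitous_threshold = 0.6), "<=")
})

test_that("categories partition genes and markers shrink as the cutoff rises", {
  sim <- tiny_sim()
  tab <- compute_auc_table(sim$counts, sim$annotation, "type")
  cls <- classify_genes(tab)
  expect_identical(nrow(cls), ncol(sim$counts))
  expect_false(any(is.na(cls$category)))
  n_marker <- vapply(c(0.6, 0.7, 0.8, 0.9, 1.0), function(th) {
    sum(classify_genes(tab, marker_threshold = th)$category == "marker")
  }, numeric(1L))
  expect_true(all(diff(n_marker) <= 0))
})

test_that("marker counts per type count shared markers once in the total", {
  tab <- make_tab(rbind(c(0.9, 0.85), c(0.95, 0.2), c(0.3, 0.4)))
  mk <- count_markers_per_type(tab)
  expect_identical(mk$per_type, c(T1 = 2L, T2 = 1L))
  expect_equal(mk$mean_per_type, 1.5)
  expect_identical(mk$total_distinct, 2L)  # shared gene counted once
  expect_error(count_markers_per_type(tab, threshold = 1.01), "\\[0, 1\\]")
})

test_that("planted markers give expected per-type counts", {
  sim <- simulate_dataset(simulation_config(n_types = 3, cells_per_type = 60,
                                            n_marker = 30, n_de = 0,
                                            n_ubiquitous = 0, seed = 5))
  tab <- compute_auc_table(sim$counts, sim$annotation, "type")
  mk <- count_markers_per_type(tab)
  expect_true(all(abs(mk$per_type - 10L) <= 1L))
  expect_gte(mk$total_distinct, 28L)
})

test_that("assignment curve excludes unassigned genes and is non-increasing", {
  tab <- make_tab(rbind(c(1.0, 0.2), c(0.5, 0.5)))
  curve <- assignment_curve(tab, cutoffs = c(0.6, 1.0))
  # the all-0.5 gene has zero assignments at 0.6 and is excluded
  expect_equal(curve$mean_types, c(1, 1))
  expect_identical(curve$n_genes, c(1L, 1L))
  counted <- assignment_curve(tab, cutoffs = c(0.6, 1.0),
                              zero_policy = "count")
  expect_equal(counted$mean_types, c(0.5, 0.5))

  sim <- tiny_sim()
  stab <- compute_auc_table(sim$counts, sim$annotation, "type")
  # per-gene assignment counts are non-increasing in the cutoff, so the
  # all-genes mean (zeros counted) is non-increasing too
  sc <- assignment_curve(stab, zero_policy = "count")
  ok <- !is.na(sc$mean_types)
  expect_true(all(diff(sc$mean_types[ok]) <= 1e-12))
  # aucmax-binned alternative stays well defined
  sb <- assignment_curve(stab, mode = "aucmax_bin")
  expect_true(all(sb$mean_types >= 1, na.rm = TRUE))
})

test_that("cell-type clustering merges identical profiles first", {
  tab <- make_tab(cbind(c(0.9, 0.1), c(0.9, 0.1), c(0.1, 0.9)),
                  types = c("A1", "A2", "B1"))
  cl <- cluster_celltypes(tab)
  merge1 <- sort(-cl$hclust$merge[1, ])
  expect_identical(cl$hclust$labels[merge1], c("A1", "A2"))
  expect_equal(cl$hclust$height[1], 0)
  expect_error(cluster_celltypes(make_tab(matrix(0.5, 2, 1))), "2 cell types")
  # single marker gene still clusters
  one <- make_tab(matrix(c(0.9, 0.1, 0.2), 1, 3))
  expect_length(cluster_celltypes(one)$order, 3L)
})

test_that("type families sharing markers cluster together", {
  # two families of two types; markers high in both types of a family
  m <- rbind(c(0.9, 0.85, 0.1, 0.15),
             c(0.88, 0.9, 0.2, 0.1),
             c(0.1, 0.2, 0.9, 0.92),
             c(0.15, 0.1, 0.87, 0.9))
  cl <- cluster_celltypes(make_tab(m, types = c("F1a", "F1b", "F2a", "F2b")))
  ord <- cl$order
  f1 <- which(ord %in% c("F1a", "F1b"))
  expect_identical(abs(diff(f1)), 1L)  # family members adjacent
})
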