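# Mann-Whitney U with mid-rank ties; exact two-sided p by the null
# rank distribution (stats::pwilcox) when tie-free and n_a * n_b is
# small, otherwise a normal approximation with tie-corrected variance
# and continuity correction.
mann_whitney <- function(a, b, exact_limit = 1000L) {
  n_a <- length(a)
  n_b <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1L)
  if (!has_ties && n_a * n_b <= exact_limit) {
    p_lo <- pwilcox(u, n_a, n_b)
    p_hi <- 1 - pwilcox(u - 1, n_a, n_b)
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    n <- n_a + n_b
    mu <- n_a * n_b / 2
    sigma2 <- (n_a * n_b / 12) *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1  # all observations tied: no evidence either way
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
  }
  list(u = u, p = p)
}

#' Compare two AUC_max distributions (two-sided Mann-Whitney U)
#'
#' The gene-set stage's basic comparison: a two-sided Mann-Whitney U
#' test between the AUC_max values of two gene sets, reported together
#' with the difference in medians (median of `values_a` minus median of
#' `values_b`). Mid-ranks handle ties; the p value is exact (null rank
#' distribution) for tie-free samples with `n_a * n_b <= exact_limit`,
#' and a tie-corrected, continuity-corrected normal approximation
#' otherwise.
#'
#' @param values_a,values_b numeric vectors (e.g. AUC_max per gene).
#' @param set_a,set_b names carried into the result.
#' @param exact_limit largest `n_a * n_b` for which the exact null
#'   distribution is used (tie-free samples only).
#' @return one-row data.frame: `set_a`, `set_b`, `n_a`, `n_b`,
#'   `u_statistic`, `p_two_sided`, `median_diff`.
#' @export
#' @examples
#' compare_sets_mannwhitney(c(0.9, 0.8), c(0.5, 0.6))  # p = 1/3
compare_sets_mannwhitney <- function(values_a, values_b,
                                     set_a = "A", set_b = "B",
                                     exact_limit = 1000L) {
  if (!length(values_a) || !length(values_b))
    stop2("both value vectors must be non-empty")
  mw <- mann_whitney(values_a, values_b, exact_limit)
  data.frame(set_a = set_a, set_b = set_b,
             n_a = length(values_a), n_b = length(values_b),
             u_statistic = mw$u, p_two_sided = mw$p,
             median_diff = median(values_a) - median(values_b),
             stringsAsFactors = FALSE)
}

#' All pairwise gene-set comparisons
#'
#' Runs [compare_sets_mannwhitney()] for every pair of sets and
#' arranges the results as matrices: a symmetric p-value matrix, the
#' antisymmetric matrix of median differences (row minus column), and
#' significance stars (`*` p < 0.05, `**` p < 0.01). Optional
#' Benjamini-Hochberg adjustment is applied across the upper triangle.
#'
#' @param sets named list of numeric vectors (AUC_max per set).
#' @param adjust `"none"` (raw p, default) or `"BH"`.
#' @return list of class `pairwise_comparison`: `p`, `neg_log10_p`,
#'   `median_diff`, `stars` matrices and a long-format `table`
#'   data.frame (upper-triangle pairs, with `p_adjusted` when
#'   requested).
#' @export
pairwise_compare <- function(sets, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(is.list(sets), length(sets) >= 2L)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop2("sets must be named")
  if (any(!lengths(sets))) stop2("empty gene set value vector")
  nm <- names(sets)
  k <- length(sets)
  p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  md <- matrix(0, k, k, dimnames = list(nm, nm))
  rows <- list()
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      res <- compare_sets_mannwhitney(sets[[i]], sets[[j]], nm[i], nm[j])
      p[i, j] <- p[j, i] <- res$p_two_sided
      md[i, j] <- res$median_diff
      md[j, i] <- -res$median_diff
      rows[[length(rows) + 1L]] <- res
    }
  }
  tab <- do.call(rbind, rows)
  if (adjust == "BH") {
    tab$p_adjusted <- p.adjust(tab$p_two_sided, method = "BH")
    for (r in seq_len(nrow(tab))) {
      i <- match(tab$set_a[r], nm)
      j <- match(tab$set_b[r], nm)
      p[i, j] <- p[j, i] <- tab$p_adjusted[r]
    }
  }
  diag(p) <- NA_real_
  stars <- matrix("", k, k, dimnames = list(nm, nm))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  structure(list(p = p, neg_log10_p = -log10(p), median_diff = md,
                 stars = stars, table = tab, adjust = adjust),
            class = "pairwise_comparison")
}

#' @export
print.pairwise_comparison <- function(x, ...) {
  cat("Pairwise Mann-Whitney comparisons (", nrow(x$p), " sets, adjust=",
      x$adjust, ")\n", sep = "")
  print(x$table, ...)
  invisible(x)
}

#' Random-gene resampling null for a gene-set statistic
#'
#' Tests whether a gene set's AUC_max summary (median by default) is
#' higher than expected for random gene sets of the same size drawn
#' without replacement from the detected-gene universe. The empirical
#' one-sided p uses the add-one rule p = (1 + #\{null >= observed\}) /
#' (B + 1), so p is never exactly zero and the floor is 1 / (B + 1).
#' With `exhaustive = TRUE` all subsets are enumerated instead and the
#' p value is the exact fraction of subsets at or above the observed
#' statistic.
#'
#' @param target_values numeric vector for the gene set under test.
#' @param universe_values numeric vector for the whole universe of
#'   detected genes.
#' @param set_size subset size drawn under the null (default: size of
#'   the target set).
#' @param B number of random draws (default 9999).
#' @param seed integer seed for reproducibility (optional).
#' @param statistic `"median"` or `"mean"`.
#' @param exhaustive enumerate all subsets (only for small universes).
#' @return list of class `resample_result`: `observed_stat`,
#'   `null_stats`, `p_empirical`, `B`, `seed`, `statistic`,
#'   `exhaustive`.
#' @export
resample_null <- function(target_values, universe_values,
                          set_size = length(target_values), B = 9999L,
                          seed = NULL, statistic = c("median", "mean"),
                          exhaustive = FALSE) {
  statistic <- match.arg(statistic)
  if (!length(target_values)) stop2("target set is empty")
  if (set_size > length(universe_values))
    stop2("set_size exceeds the universe size")
  stat <- if (statistic == "median") median else mean
  observed <- stat(target_values)
  if (exhaustive) {
    n_sub <- choose(length(universe_values), set_size)
    if (n_sub > 2e5) stop2("exhaustive mode infeasible: ", n_sub, " subsets")
    null_stats <- combn(universe_values, set_size, stat)
    p <- sum(null_stats >= observed) / length(null_stats)
    B_eff <- length(null_stats)
  } else {
    if (B < 1L) stop2("B must be >= 1")
    null_stats <- with_seed(seed, vapply(seq_len(B), function(b) {
      stat(sample(universe_values, set_size))
    }, numeric(1L)))
    p <- (1 + sum(null_stats >= observed)) / (B + 1)
    B_eff <- B
  }
  structure(list(observed_stat = observed, null_stats = null_stats,
                 p_empirical = p, B = B_eff, seed = seed,
                 statistic = statistic, exhaustive = exhaustive),
            class = "resample_result")
}

#' @export
print.resample_result <- function(x, ...) {
  cat(sprintf("Resampling null (%s%s, B=%d): observed=%.4f, p=%.3g\n",
              x$statistic, if (x$exhaustive) ", exhaustive" else "",
              x$B, x$observed_stat, x$p_empirical))
  invisible(x)
}

#' Genetic-constraint summary of a gene set
#'
#' Summarizes loss-of-function constraint (LOEUF) over the members of a
#' gene set found in a constraint table: the median LOEUF, the fraction
#' of matched genes strictly above the constraint threshold (LOEUF >
#' 0.6 means not intolerant to haploinsufficiency), and how many set
#' members matched. Matching is case-insensitive; unmatched genes are
#' reported, not fatal.
#'
#' @param genes character vector of gene symbols (one gene set).
#' @param constraint data.frame from [read_constraint_table()] (columns
#'   `gene`, `loeuf`).
#' @param constraint_threshold LOEUF cutoff (default 0.6).
#' @return list: `median_loeuf`, `frac_above_threshold`, `n_matched`,
#'   `n_unmatched`, `unmatched` (symbols).
#' @export
constraint_summary <- function(genes, constraint,
                               constraint_threshold = 0.6) {
  stopifnot(is.data.frame(constraint),
            all(c("gene", "loeuf") %in% names(constraint)))
  genes <- unique(normalize_symbols(genes))
  idx <- match(genes, normalize_symbols(constraint$gene))
  matched <- !is.na(idx)
  if (!any(matched)) stop2("no gene of the set is in the constraint table")
  loeuf <- constraint$loeuf[idx[matched]]
  list(median_loeuf = median(loeuf),
       frac_above_threshold = mean(loeuf > constraint_threshold),
       n_matched = sum(matched),
       n_unmatched = sum(!matched),
       unmatched = genes[!matched])
}

#' Cross-dataset consistency of AUC_max distributions
#'
#' For each gene set, compares the set's AUC_max values computed in two
#' datasets with a two-sided Mann-Whitney U test. Non-significant
#' results indicate that the specificity profile of the set replicates
#' across datasets.
#'
#' @param aucmax_a,aucmax_b named numeric vectors of AUC_max per gene
#'   in each dataset (names are gene symbols).
#' @param gene_sets named list of character vectors.
#' @return data.frame, one row per set, with columns of
#'   [compare_sets_mannwhitney()] plus `set`, `n_genes_a`, `n_genes_b`.
#' @export
cross_dataset_consistency <- function(aucmax_a, aucmax_b, gene_sets) {
  stopifnot(!is.null(names(aucmax_a)), !is.null(names(aucmax_b)),
            is.list(gene_sets), length(gene_sets) >= 1L)
  names(aucmax_a) <- normalize_symbols(names(aucmax_a))
  names(aucmax_b) <- normalize_symbols(names(aucmax_b))
  rows <- lapply(names(gene_sets), function(nm) {
    genes <- normalize_symbols(gene_sets[[nm]])
    va <- aucmax_a[intersect(genes, names(aucmax_a))]
    vb <- aucmax_b[intersect(genes, names(aucmax_b))]
    if (!length(va) || !length(vb))
      stop2("gene set '", nm, "' has no detected gene in one dataset")
    res <- compare_sets_mannwhitney(va, vb, "dataset_a", "dataset_b")
    cbind(set = nm, res)
  })
  do.call(rbind, rows)
}
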