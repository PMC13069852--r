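#' One-vs-rest ROC curve for a gene
#'
#' Builds the ROC curve that underlies the specificity AUC: for each
#' distinct observed count threshold t (descending, plus a sentinel
#' below the minimum), TPR(t) is the fraction of target-type cells with
#' counts strictly greater than t and FPR(t) the same fraction among
#' all other cells. The curve is anchored at (0, 0) and reaches (1, 1)
#' at the sentinel.
#'
#' @param pos_counts counts of the gene in cells of the target type.
#' @param neg_counts counts of the gene in all other cells.
#' @return object of class `roc_curve`: list with `thresholds`
#'   (descending, sentinel last) and `fpr`, `tpr` (one leading anchor
#'   point, so one element longer than `thresholds`).
#' @seealso [auc_trapezoid()], [auc_rank()]
#' @export
#' @examples
#' roc_curve(c(5, 3, 0), c(2, 0, 0, 1))
roc_curve <- function(pos_counts, neg_counts) {
  if (!length(pos_counts) || !length(neg_counts))
    stop2("both groups must be non-empty")
  thr <- sort(unique(c(pos_counts, neg_counts)), decreasing = TRUE)
  thr <- c(thr, thr[length(thr)] - 1)  # sentinel below the minimum
  tpr <- vapply(thr, function(t) mean(pos_counts > t), numeric(1L))
  fpr <- vapply(thr, function(t) mean(neg_counts > t), numeric(1L))
  structure(list(thresholds = thr, fpr = c(0, fpr), tpr = c(0, tpr)),
            class = "roc_curve")
}

#' Area under a ROC curve by the trapezoidal rule
#'
#' @param curve a [roc_curve()].
#' @return AUC in \[0, 1\].
#' @export
auc_trapezoid <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  fpr <- curve$fpr
  tpr <- curve$tpr
  sum(diff(fpr) * (head(tpr, -1L) + tail(tpr, -1L)) / 2)
}

#' Rank-based AUC (Mann-Whitney form)
#'
#' Computes the same AUC as [auc_trapezoid()] over the full threshold
#' sweep, as U / (n_pos * n_neg) with mid-ranks for ties: the
#' probability that a random target-type cell expresses the gene more
#' highly than a random other cell, ties counted half. The two routes
#' agree exactly and the equality is enforced by the test suite.
#'
#' @inheritParams roc_curve
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' auc_rank(c(5, 3, 0), c(2, 0, 0, 1))  # 0.75
auc_rank <- function(pos_counts, neg_counts) {
  n_pos <- length(pos_counts)
  n_neg <- length(neg_counts)
  if (!n_pos || !n_neg) stop2("both groups must be non-empty")
  r <- rank(c(pos_counts, neg_counts))
  (sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

new_auc_table <- function(auc, level, n_cells_per_type = NULL) {
  structure(auc, level = level, n_cells_per_type = n_cells_per_type,
            class = c("auc_table", class(auc)))
}

#' @export
print.auc_table <- function(x, ...) {
  cat("AUC table:", nrow(x), "genes x", ncol(x), "cell types",
      sprintf("(level '%s')\n", attr(x, "level")))
  print(head(unclass(x), 5L), ...)
  if (nrow(x) > 5L) cat("...\n")
  invisible(x)
}

#' Compute the genes x cell-types AUC table
#'
#' For every gene and every label of the chosen annotation level,
#' computes the one-vs-rest AUC of the gene's raw counts: cells of the
#' label against all other annotated cells. This is the sparse-aware
#' production path; it ranks only the nonzero entries of each gene and
#' handles the tied zeros analytically, and equals
#' `auc_trapezoid(roc_curve(...))` entry for entry.
#'
#' AUC is rank-based, hence invariant to any per-gene monotone
#' transformation of counts, but not to per-cell depth scaling;
#' `normalize_depth = TRUE` divides each cell's counts by its total
#' count first (off by default: the statistic is defined on raw read
#' counts).
#'
#' @param counts cells x genes count matrix ([expression_matrix()]).
#' @param annotation data.frame from [read_cell_annotation()] (or the
#'   simulator) with `cell_id` and the level column.
#' @param level name of the annotation column to use.
#' @param genes optional subset of gene symbols; unknown symbols are
#'   reported and skipped.
#' @param normalize_depth divide counts by per-cell totals first.
#' @return an `auc_table`: genes x types matrix of AUCs in \[0, 1\] with
#'   attributes `level` and `n_cells_per_type`.
#' @export
compute_auc_table <- function(counts, annotation, level, genes = NULL,
                              normalize_depth = FALSE) {
  stopifnot(is.data.frame(annotation), "cell_id" %in% names(annotation))
  if (!level %in% names(annotation))
    stop2("annotation has no level column '", level, "'")
  counts <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  idx <- match(annotation$cell_id, rownames(counts))
  if (all(is.na(idx))) stop2("no annotated cell found in the count matrix")
  lab <- annotation[[level]]
  keep <- !is.na(idx) & !is.na(lab) & nzchar(lab)
  dropped <- sum(!keep)
  if (dropped > 0L)
    message(dropped, " cell(s) without a usable '", level,
            "' label dropped from this level")
  counts <- counts[idx[keep], , drop = FALSE]
  lab <- factor(lab[keep])
  if (nlevels(lab) < 2L)
    stop2("level '", level, "' has fewer than 2 distinct labels")
  if (!is.null(genes)) {
    genes <- normalize_symbols(genes)
    unknown <- setdiff(genes, colnames(counts))
    if (length(unknown))
      warning(length(unknown), " requested gene(s) not in the matrix, ",
              "skipped: ", paste(head(unknown, 5L), collapse = ", "),
              call. = FALSE)
    genes <- intersect(genes, colnames(counts))
    if (!length(genes)) stop2("empty intersection of requested genes")
    counts <- counts[, genes, drop = FALSE]
  }
  if (normalize_depth) {
    depth <- Matrix::rowSums(counts)
    depth[depth == 0] <- 1
    counts <- counts / depth  # keeps zero pattern; values stay positive
    counts <- as(as(counts, "generalMatrix"), "CsparseMatrix")
  }
  n <- nrow(counts)
  type_idx <- as.integer(lab)
  n_per_type <- tabulate(type_idx, nlevels(lab))
  auc <- matrix(NA_real_, ncol(counts), nlevels(lab),
                dimnames = list(colnames(counts), levels(lab)))
  p <- counts@p
  i <- counts@i
  x <- counts@x
  for (g in seq_len(ncol(counts))) {
    sel <- if (p[g + 1L] > p[g]) (p[g] + 1L):p[g + 1L] else integer(0)
    rows <- i[sel] + 1L
    nz <- length(rows)
    n0 <- n - nz
    # ranks over all cells: zeros tie at (n0 + 1) / 2, nonzeros above
    r_nz <- n0 + rank(x[sel])
    rs_nz <- rowsum_by(r_nz, type_idx[rows], nlevels(lab))
    nz_per_type <- tabulate(type_idx[rows], nlevels(lab))
    rank_sum <- rs_nz + (n_per_type - nz_per_type) * (n0 + 1) / 2
    auc[g, ] <- (rank_sum - n_per_type * (n_per_type + 1) / 2) /
      (n_per_type * (n - n_per_type))
  }
  new_auc_table(auc, level = level,
                n_cells_per_type = setNames(n_per_type, levels(lab)))
}

rowsum_by <- function(values, group, ngroups) {
  out <- numeric(ngroups)
  if (length(values)) {
    s <- rowsum(values, group)
    out[as.integer(rownames(s))] <- s[, 1L]
  }
  out
}

#' Detected genes
#'
#' A gene counts as detected when it has a nonzero count in at least
#' `min_cells` cells (default 1).
#'
#' @param counts cells x genes count matrix.
#' @param min_cells minimum number of cells with nonzero counts.
#' @return character vector of detected gene symbols.
#' @export
detect_genes <- function(counts, min_cells = 1L) {
  stopifnot(min_cells >= 1L)
  counts <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  nnz <- diff(counts@p)
  colnames(counts)[nnz >= min_cells]
}
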