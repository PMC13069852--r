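#' Per-gene maximum AUC and best cell type
#'
#' The specificity summary of a gene at a hierarchy level is the
#' maximum of its one-vs-rest AUCs across cell types (AUC_max) together
#' with the type achieving it. Ties are broken by the first type in
#' table order and reported with a message.
#'
#' @param table an `auc_table`.
#' @return data.frame with columns `gene`, `auc_max`, `best_type`.
#' @export
auc_max <- function(table) {
  stopifnot(is.matrix(table))
  if (!nrow(table) || !ncol(table)) stop2("empty AUC table")
  m <- unclass(table)
  best <- max.col(m, ties.method = "first")
  amax <- m[cbind(seq_len(nrow(m)), best)]
  n_tied <- sum(rowSums(m == amax) > 1L)
  if (n_tied > 0L)
    message(n_tied, " gene(s) with tied AUC_max; first type in table ",
            "order kept")
  data.frame(gene = rownames(m), auc_max = amax,
             best_type = colnames(m)[best], stringsAsFactors = FALSE)
}

#' Classify genes along the marker / DE / ubiquitous gradient
#'
#' Genes with AUC_max at or above `marker_threshold` are candidate
#' markers; genes with AUC_max below `ubiquitous_threshold` are
#' ubiquitous; the rest are intermediate (preferentially expressed in a
#' few types). Boundary semantics follow the defining inequalities:
#' AUC_max exactly 0.8 is a marker, exactly 0.6 is intermediate.
#'
#' @param x an `auc_table`, the data.frame from [auc_max()], or a named
#'   numeric vector of AUC_max values.
#' @param marker_threshold candidate-marker cutoff (default 0.8).
#' @param ubiquitous_threshold ubiquitous cutoff (default 0.6).
#' @return data.frame with `gene`, `auc_max`, `best_type` (NA when `x`
#'   is a bare vector) and `category` (factor: marker / intermediate /
#'   ubiquitous).
#' @export
#' @examples
#' classify_genes(c(A = 0.91, B = 0.70, C = 0.55))
classify_genes <- function(x, marker_threshold = 0.8,
                           ubiquitous_threshold = 0.6) {
  if (!(ubiquitous_threshold >= 0 && ubiquitous_threshold <= marker_threshold &&
        marker_threshold <= 1))
    stop2("need 0 <= ubiquitous_threshold <= marker_threshold <= 1")
  if (inherits(x, "auc_table")) x <- auc_max(x)
  if (is.numeric(x)) {
    x <- data.frame(gene = if (is.null(names(x)))
      as.character(seq_along(x)) else names(x),
      auc_max = unname(x), best_type = NA_character_,
      stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(x), all(c("gene", "auc_max") %in% names(x)))
  category <- ifelse(x$auc_max >= marker_threshold, "marker",
                     ifelse(x$auc_max < ubiquitous_threshold,
                            "ubiquitous", "intermediate"))
  x$category <- factor(category,
                       levels = c("marker", "intermediate", "ubiquitous"))
  x
}

#' Candidate-marker counts per cell type
#'
#' A gene counts as a marker for a type when its AUC for that type is
#' at or above the threshold; a gene exceeding the threshold in several
#' types is counted in each of them but only once in the distinct
#' total.
#'
#' @param table an `auc_table`.
#' @param threshold candidate-marker AUC cutoff (default 0.8).
#' @return list with `per_type` (named integer vector),
#'   `mean_per_type`, and `total_distinct`.
#' @export
count_markers_per_type <- function(table, threshold = 0.8) {
  stopifnot(is.matrix(table))
  if (threshold < 0 || threshold > 1) stop2("threshold must be in [0, 1]")
  hit <- unclass(table) >= threshold
  list(per_type = setNames(as.integer(colSums(hit)), colnames(table)),
       mean_per_type = mean(colSums(hit)),
       total_distinct = sum(rowSums(hit) > 0L))
}

#' Mean number of cell types assigned per gene, across AUC cutoffs
#'
#' For each cutoff x, a gene is assigned to every cell type for which
#' its AUC is at least x; the curve reports the mean and SD of the
#' number of assignments per gene. By default genes with zero
#' assignments at a cutoff are excluded from that cutoff's mean
#' (`zero_policy = "count"` includes them as zeros instead). The
#' `"aucmax_bin"` mode groups genes by the grid bin of their AUC_max
#' and reports, per bin, assignments at the bin's lower edge.
#'
#' @param table an `auc_table`.
#' @param cutoffs increasing grid of AUC cutoffs in \[0.5, 1\].
#' @param zero_policy `"exclude"` (default) or `"count"` genes with no
#'   assignment.
#' @param mode `"cutoff"` (default) or `"aucmax_bin"`.
#' @return data.frame with `cutoff`, `mean_types`, `sd_types`,
#'   `n_genes`.
#' @export
assignment_curve <- function(table, cutoffs = seq(0.5, 1, by = 0.01),
                             zero_policy = c("exclude", "count"),
                             mode = c("cutoff", "aucmax_bin")) {
  stopifnot(is.matrix(table))
  zero_policy <- match.arg(zero_policy)
  mode <- match.arg(mode)
  m <- unclass(table)
  cutoffs <- sort(cutoffs)
  if (mode == "aucmax_bin") {
    amax <- apply(m, 1L, max)
    bin <- findInterval(amax, cutoffs)
  }
  rows <- lapply(seq_along(cutoffs), function(k) {
    x <- cutoffs[k]
    counts <- rowSums(m >= x)
    if (mode == "aucmax_bin") counts <- counts[bin == k]
    if (zero_policy == "exclude") counts <- counts[counts > 0L]
    data.frame(cutoff = x,
               mean_types = if (length(counts)) mean(counts) else NA_real_,
               sd_types = if (length(counts) > 1L) sd(counts) else NA_real_,
               n_genes = length(counts))
  })
  do.call(rbind, rows)
}

#' Cluster cell types on their marker AUC profiles
#'
#' Hierarchically clusters the cell-type columns of an AUC table
#' (typically restricted to a marker panel) using Euclidean distance
#' between AUC vectors and average linkage. Deterministic: no
#' randomness is involved.
#'
#' @param table an `auc_table`.
#' @param genes optional marker panel (row subset) to cluster on.
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return list with `hclust` (the dendrogram) and `order` (cell-type
#'   labels in dendrogram order).
#' @export
cluster_celltypes <- function(table, genes = NULL, linkage = "average") {
  stopifnot(is.matrix(table))
  m <- unclass(table)
  if (!is.null(genes)) {
    genes <- intersect(normalize_symbols(genes), rownames(m))
    if (!length(genes)) stop2("no requested marker gene found in the table")
    m <- m[genes, , drop = FALSE]
  }
  if (ncol(m) < 2L) stop2("need at least 2 cell types to cluster")
  hc <- hclust(dist(t(m)), method = linkage)
  list(hclust = hc, order = colnames(m)[hc$order])
}
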