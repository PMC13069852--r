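#' Construct a cells x genes expression matrix
#'
#' The package's central container is a sparse, zero-dominated matrix of
#' raw read/UMI counts with cells in rows and genes in columns. This
#' constructor coerces to `dgCMatrix`, attaches identifiers and enforces
#' the contract: all entries non-negative integers, identifiers unique
#' (gene symbols unique after case normalization).
#'
#' Duplicate gene symbols are collapsed by keeping, for each symbol, the
#' column with the highest total count; a warning reports how many were
#' dropped.
#'
#' @param counts numeric matrix or `Matrix`, cells x genes, raw counts.
#' @param cell_ids character vector of cell identifiers (default:
#'   rownames of `counts`).
#' @param gene_ids character vector of gene symbols (default: colnames).
#' @return a `dgCMatrix` with cells in rows and normalized gene symbols
#'   as column names.
#' @export
#' @examples
#' m <- expression_matrix(rbind(c(0, 5), c(1, 0), c(2, 2)),
#'                        cell_ids = paste0("C", 1:3),
#'                        gene_ids = c("GeneA", "GeneB"))
#' dim(m)
expression_matrix <- function(counts, cell_ids = rownames(counts),
                              gene_ids = colnames(counts)) {
  if (is.null(cell_ids) || is.null(gene_ids))
    stop2("cell_ids and gene_ids are required (or set dimnames on counts)")
  m <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (nrow(m) == 0L || ncol(m) == 0L) stop2("empty count matrix")
  if (length(cell_ids) != nrow(m))
    stop2("cell_ids length (", length(cell_ids),
          ") does not match number of rows (", nrow(m), ")")
  if (length(gene_ids) != ncol(m))
    stop2("gene_ids length (", length(gene_ids),
          ") does not match number of columns (", ncol(m), ")")
  if (anyDuplicated(cell_ids)) stop2("duplicated cell ids")
  x <- m@x
  if (length(x)) {
    if (any(x < 0)) stop2("negative counts are not allowed")
    if (any(abs(x - round(x)) > 1e-8)) stop2("non-integer counts are not allowed")
  }
  gene_ids <- normalize_symbols(gene_ids)
  if (anyDuplicated(gene_ids)) {
    totals <- Matrix::colSums(m)
    keep <- unsplit(lapply(split(seq_along(gene_ids), gene_ids), function(i) {
      i == i[which.max(totals[i])]
    }), gene_ids)
    warning(sum(!keep), " duplicated gene symbol column(s) dropped; ",
            "kept the highest-count column per symbol", call. = FALSE)
    m <- m[, keep, drop = FALSE]
    gene_ids <- gene_ids[keep]
  }
  dimnames(m) <- list(as.character(cell_ids), gene_ids)
  m
}
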