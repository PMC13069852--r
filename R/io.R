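#' Read a count matrix from MatrixMarket or a dense table
#'
#' Supports the 10x-style MatrixMarket triplet (matrix file plus a genes
#' file and a barcodes file; on disk the matrix is genes x cells and is
#' transposed on read) and dense delimited tables with a header row and
#' an identifier column. The returned matrix always has cells in rows
#' and genes in columns.
#'
#' @param path path to the `.mtx` file or the dense table.
#' @param format `"auto"` (by extension), `"mtx"` or `"dense"`.
#' @param genes_file,barcodes_file companion files for MTX input;
#'   default to `genes.tsv` / `features.tsv` and `barcodes.tsv` next to
#'   `path`. The first column of each is used.
#' @param cells_in_rows for dense input, whether rows are cells
#'   (default TRUE); set FALSE for genes-in-rows tables.
#' @return a cells x genes sparse count matrix (see
#'   [expression_matrix()]).
#' @export
read_counts <- function(path, format = c("auto", "mtx", "dense"),
                        genes_file = NULL, barcodes_file = NULL,
                        cells_in_rows = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop2("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.mtx(\\.gz)?$", path)) "mtx" else "dense"
  if (format == "mtx") {
    dir <- dirname(path)
    if (is.null(genes_file)) {
      for (cand in c("genes.tsv", "features.tsv")) {
        if (file.exists(file.path(dir, cand)))
          genes_file <- file.path(dir, cand)
      }
    }
    if (is.null(barcodes_file) && file.exists(file.path(dir, "barcodes.tsv")))
      barcodes_file <- file.path(dir, "barcodes.tsv")
    if (is.null(genes_file) || is.null(barcodes_file))
      stop2("MTX input needs genes and barcodes files")
    m <- Matrix::readMM(path)          # genes x cells on disk
    genes <- fread(genes_file, header = FALSE, sep = "\t")[[1L]]
    cells <- fread(barcodes_file, header = FALSE, sep = "\t")[[1L]]
    if (length(genes) != nrow(m))
      stop2("genes file has ", length(genes), " entries but matrix has ",
            nrow(m), " gene rows")
    if (length(cells) != ncol(m))
      stop2("barcodes file has ", length(cells), " entries but matrix has ",
            ncol(m), " cell columns")
    expression_matrix(Matrix::t(m), cell_ids = cells, gene_ids = genes)
  } else {
    dt <- fread(path, header = TRUE)
    ids <- as.character(dt[[1L]])
    m <- as.matrix(dt[, -1L, drop = FALSE])
    if (!cells_in_rows) {
      m <- t(m)
      expression_matrix(m, cell_ids = colnames(dt)[-1L], gene_ids = ids)
    } else {
      expression_matrix(m, cell_ids = ids, gene_ids = colnames(dt)[-1L])
    }
  }
}

#' Read per-cell annotation labels
#'
#' Reads a delimited table assigning each cell to labels at one or more
#' hierarchy levels (e.g. class, subclass, cluster). Levels with a
#' single distinct label are accepted here; they are rejected when an
#' AUC table is requested for them.
#'
#' @param path delimited table with a header.
#' @param cell_col name of the cell-identifier column (default `"cell"`;
#'   falls back to the first column with a message if absent).
#' @param levels character vector of level-column names to keep;
#'   default: all non-id columns.
#' @return data.frame with column `cell_id` plus one column per level.
#' @export
read_cell_annotation <- function(path, cell_col = "cell", levels = NULL) {
  if (!file.exists(path)) stop2("file not found: ", path)
  dt <- fread(path, header = TRUE)
  if (!cell_col %in% names(dt)) {
    message("column '", cell_col, "' not found; using first column '",
            names(dt)[1L], "' as cell id")
    cell_col <- names(dt)[1L]
  }
  if (is.null(levels)) levels <- setdiff(names(dt), cell_col)
  missing_cols <- setdiff(levels, names(dt))
  if (length(missing_cols))
    stop2("annotation level column(s) absent: ",
          paste(missing_cols, collapse = ", "))
  ids <- as.character(dt[[cell_col]])
  if (anyDuplicated(ids))
    stop2("duplicated cell ids in annotation: ",
          paste(head(unique(ids[duplicated(ids)]), 3L), collapse = ", "))
  out <- data.frame(cell_id = ids, stringsAsFactors = FALSE)
  for (lv in levels) out[[lv]] <- as.character(dt[[lv]])
  out
}

#' Read gene sets from GMT or a two-column table
#'
#' GMT lines are `name<TAB>description<TAB>gene1<TAB>gene2...`; the
#' two-column dialect has one `(set, gene)` pair per row (an optional
#' `set`/`gene` header row is skipped). Symbols are case-normalized;
#' sets may overlap. Empty sets are an error.
#'
#' @param path gene-set file.
#' @param format `"auto"`, `"gmt"` or `"tsv"`.
#' @return named list of character vectors of gene symbols.
#' @export
read_gene_sets <- function(path, format = c("auto", "gmt", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop2("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop2("empty gene-set file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "auto")
    format <- if (grepl("\\.gmt$", path) || any(lengths(fields) >= 3L))
      "gmt" else "tsv"
  sets <- list()
  if (format == "gmt") {
    for (f in fields) {
      if (length(f) < 3L)
        stop2("unparseable GMT line (need name, description, >=1 gene): ",
              paste(f, collapse = "\t"))
      genes <- unique(normalize_symbols(f[-(1:2)]))
      genes <- genes[nzchar(genes)]
      if (!length(genes)) stop2("gene set '", f[1L], "' is empty")
      sets[[f[1L]]] <- genes
    }
  } else {
    if (any(lengths(fields) != 2L))
      stop2("two-column gene-set table has a malformed line")
    tab <- do.call(rbind, fields)
    if (identical(tolower(tab[1L, ]), c("set", "gene")))
      tab <- tab[-1L, , drop = FALSE]
    if (!nrow(tab)) stop2("empty gene-set table")
    sets <- lapply(split(normalize_symbols(tab[, 2L]), tab[, 1L]), unique)
    if (any(!lengths(sets))) stop2("empty gene set in table")
  }
  sets
}

#' Read a gene constraint (LOEUF) table
#'
#' Expects a delimited table with columns `gene` and `loeuf` (matched
#' case-insensitively; extra columns ignored), e.g. a gnomAD export.
#' LOEUF values must be finite and non-negative; duplicated symbols keep
#' the first row with a warning.
#'
#' @param path delimited table with a header.
#' @return data.frame with columns `gene` (normalized symbol) and
#'   `loeuf`.
#' @export
read_constraint_table <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  dt <- fread(path, header = TRUE)
  gcol <- which(tolower(names(dt)) == "gene")[1L]
  lcol <- which(tolower(names(dt)) == "loeuf")[1L]
  if (is.na(gcol) || is.na(lcol))
    stop2("constraint table needs 'gene' and 'loeuf' columns")
  out <- data.frame(gene = normalize_symbols(dt[[gcol]]),
                    loeuf = as.numeric(dt[[lcol]]),
                    stringsAsFactors = FALSE)
  if (any(!is.finite(out$loeuf)) || any(out$loeuf < 0))
    stop2("LOEUF values must be finite and non-negative")
  if (anyDuplicated(out$gene)) {
    warning("duplicated gene symbols in constraint table; keeping first",
            call. = FALSE)
    out <- out[!duplicated(out$gene), ]
  }
  out
}

#' Write / read an AUC table
#'
#' The on-disk form is a TSV with genes in rows, cell types in columns
#' and full double precision, preceded by comment lines (`# level=`,
#' `# n_cells=`) carrying the hierarchy level and per-type cell counts,
#' so that a write-read round trip reproduces the object exactly.
#'
#' @param table an `auc_table` (see [compute_auc_table()]) for writing.
#' @param path output / input file.
#' @return `write_auc_table` returns `path` invisibly; `read_auc_table`
#'   returns an `auc_table`.
#' @export
write_auc_table <- function(table, path) {
  stopifnot(is.matrix(table))
  if (!nrow(table) || !ncol(table)) stop2("empty AUC table")
  con <- file(path, "w")
  on.exit(close(con))
  lvl <- attr(table, "level")
  ncp <- attr(table, "n_cells_per_type")
  if (!is.null(lvl)) writeLines(paste0("# level=", lvl), con)
  if (!is.null(ncp))
    writeLines(paste0("# n_cells=", paste(names(ncp), ncp, sep = ":",
                                          collapse = ",")), con)
  writeLines(paste(c("gene", colnames(table)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(table)), function(i) {
    paste(c(rownames(table)[i], sprintf("%.17g", table[i, ])),
          collapse = "\t")
  }, character(1L))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_auc_table
#' @export
read_auc_table <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^#", lines, value = TRUE)
  lines <- grep("^#", lines, value = TRUE, invert = TRUE)
  if (length(lines) < 2L) stop2("empty AUC table: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  if (any(lengths(body) != length(header))) stop2("ragged AUC table")
  genes <- vapply(body, `[`, character(1L), 1L)
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1L]),
           numeric(length(header) - 1L)))
  m <- matrix(vals, nrow = length(genes), ncol = length(header) - 1L,
              byrow = TRUE, dimnames = list(genes, header[-1L]))
  if (any(is.na(m)) || any(m < 0) || any(m > 1))
    stop2("AUC values must be numbers in [0, 1]")
  lvl <- sub("^# level=", "", grep("^# level=", meta, value = TRUE))
  ncp_line <- sub("^# n_cells=", "", grep("^# n_cells=", meta, value = TRUE))
  ncp <- NULL
  if (length(ncp_line)) {
    parts <- strsplit(strsplit(ncp_line[1L], ",", fixed = TRUE)[[1L]],
                      ":", fixed = TRUE)
    ncp <- setNames(as.integer(vapply(parts, `[`, character(1L), 2L)),
                    vapply(parts, `[`, character(1L), 1L))
  }
  new_auc_table(m, level = if (length(lvl)) lvl[1L] else NA_character_,
                n_cells_per_type = ncp)
}
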