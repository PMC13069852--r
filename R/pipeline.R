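#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param description description field written on every line.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path, description = "aucmarker") {
  stopifnot(is.list(sets), length(sets) >= 1L, !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

write_counts_mtx <- function(counts, dir) {
  # 10x dialect: genes x cells on disk
  Matrix::writeMM(Matrix::t(counts), file.path(dir, "counts.mtx"))
  writeLines(colnames(counts), file.path(dir, "genes.tsv"))
  writeLines(rownames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Run the full simulate - AUC - classify - compare pipeline
#'
#' Simulates a labeled dataset, computes the one-vs-rest AUC table at
#' the requested level, classifies genes along the marker /
#' intermediate / ubiquitous gradient, compares role-based gene sets
#' (pairwise Mann-Whitney on AUC_max plus a random-gene resampling null
#' for the marker-rich set) and summarizes simulated LOEUF constraint.
#' All artifacts are written as TSV / MatrixMarket under `out_dir`,
#' together with a JSON manifest (package version, seed, effective
#' configuration, md5 checksum per output). Identical seeds give
#' byte-identical tabular outputs.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [simulation_config()].
#' @param seed optional seed overriding `config$seed`.
#' @param level annotation level for the AUC table (`"type"`, or
#'   `"class"` when the config groups types into classes).
#' @param marker_threshold,ubiquitous_threshold classification cutoffs.
#' @param resamples draws for the resampling null.
#' @param gene_sets optional named list of gene symbol vectors to use
#'   instead of the role-derived sets.
#' @param constraint optional constraint data.frame (columns `gene`,
#'   `loeuf`) instead of the simulated one.
#' @return invisible list with the in-memory results (`sim`, `auc`,
#'   `classification`, `comparison`, `resample`, `constraint_summary`,
#'   `paths`).
#' @export
run_pipeline <- function(out_dir, config = simulation_config(),
                         seed = NULL, level = "type",
                         marker_threshold = 0.8,
                         ubiquitous_threshold = 0.6, resamples = 999L,
                         gene_sets = NULL, constraint = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  sim <- simulate_dataset(config)
  write_counts_mtx(sim$counts, out_dir)
  write_tsv(sim$annotation, file.path(out_dir, "cells.tsv"))
  write_tsv(sim$truth, file.path(out_dir, "truth.tsv"))

  if (is.null(gene_sets)) {
    scheme <- list()
    if (config$n_marker > 0L) scheme$marker_rich <- list(roles = "marker")
    if (config$n_de > 0L) scheme$preferential <- list(roles = "de")
    if (config$n_ubiquitous > 0L)
      scheme$ubiquitous <- list(roles = "ubiquitous")
    gene_sets <- simulate_gene_sets(sim$truth, scheme, seed = config$seed)
  }
  write_gene_sets(gene_sets, file.path(out_dir, "gene_sets.gmt"))
  if (is.null(constraint))
    constraint <- simulate_constraint_table(sim$truth, seed = config$seed)
  write_tsv(constraint, file.path(out_dir, "constraint.tsv"))

  auc <- compute_auc_table(sim$counts, sim$annotation, level = level)
  write_auc_table(auc, file.path(out_dir, "auc_table.tsv"))

  cls <- classify_genes(auc, marker_threshold, ubiquitous_threshold)
  write_tsv(cls, file.path(out_dir, "classification.tsv"))
  mk <- count_markers_per_type(auc, marker_threshold)
  write_tsv(data.frame(cell_type = names(mk$per_type),
                       n_markers = as.integer(mk$per_type)),
            file.path(out_dir, "markers_per_type.tsv"))
  curve <- assignment_curve(auc)
  write_tsv(curve, file.path(out_dir, "assignment_curve.tsv"))

  detected <- detect_genes(sim$counts)
  amax <- setNames(cls$auc_max, cls$gene)
  set_values <- lapply(names(gene_sets), function(nm) {
    v <- amax[intersect(normalize_symbols(gene_sets[[nm]]),
                        intersect(names(amax), detected))]
    if (!length(v))
      stop2("empty intersection: no gene of set '", nm,
            "' detected in the matrix")
    v
  })
  names(set_values) <- names(gene_sets)
  comparison <- pairwise_compare(set_values)
  write_tsv(comparison$table, file.path(out_dir, "comparison.tsv"))

  universe <- amax[intersect(names(amax), detected)]
  rs_set <- names(gene_sets)[1L]
  rs <- resample_null(set_values[[rs_set]], universe, B = resamples,
                      seed = config$seed)
  write_tsv(data.frame(set = rs_set, statistic = rs$statistic,
                       observed = rs$observed_stat, B = rs$B,
                       p_empirical = rs$p_empirical),
            file.path(out_dir, "resample.tsv"))

  cons <- lapply(names(gene_sets), function(nm) {
    s <- constraint_summary(gene_sets[[nm]], constraint)
    data.frame(set = nm, median_loeuf = s$median_loeuf,
               frac_above_threshold = s$frac_above_threshold,
               n_matched = s$n_matched, n_unmatched = s$n_unmatched)
  })
  cons <- do.call(rbind, cons)
  write_tsv(cons, file.path(out_dir, "constraint_summary.tsv"))

  outputs <- c("counts.mtx", "genes.tsv", "barcodes.tsv", "cells.tsv",
               "truth.tsv", "gene_sets.gmt", "constraint.tsv",
               "auc_table.tsv", "classification.tsv",
               "markers_per_type.tsv", "assignment_curve.tsv",
               "comparison.tsv", "resample.tsv", "constraint_summary.tsv")
  manifest <- list(
    package = "aucmarker",
    version = as.character(packageVersion("aucmarker")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    level = level,
    marker_threshold = marker_threshold,
    ubiquitous_threshold = ubiquitous_threshold,
    resamples = resamples,
    config = unclass(config),
    checksums = as.list(tools::md5sum(file.path(out_dir, outputs))))
  names(manifest$checksums) <- outputs
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(sim = sim, auc = auc, classification = cls,
                 comparison = comparison, resample = rs,
                 constraint_summary = cons,
                 paths = file.path(out_dir, c(outputs, "manifest.json"))))
}
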