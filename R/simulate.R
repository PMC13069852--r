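#' Configuration for the labeled count simulator
#'
#' The simulator plants three kinds of genes across a set of cell
#' types, matching the expression archetypes the AUC statistic is built
#' to separate:
#'
#' * marker genes: high mean (`marker_mean_in`, default 10) in exactly
#'   one target type, near zero (`marker_mean_out`, default 0.1)
#'   elsewhere;
#' * DE (preferentially expressed) genes: basal mean
#'   (`de_baseline_mean`, default 1) everywhere, multiplied by
#'   `de_fold` (default 4) in 1-3 target types;
#' * ubiquitous genes: the same mean (`ubiq_mean`, default 2) in every
#'   type.
#'
#' Counts are negative binomial with the given `dispersion` (size
#' parameter; `Inf` gives Poisson) around a per-cell depth factor drawn
#' log-uniformly from `depth_factor_range`, applied multiplicatively to
#' all genes of a cell.
#'
#' @param n_types number of cell types (>= 2).
#' @param cells_per_type cells simulated per type (>= 10).
#' @param n_marker,n_de,n_ubiquitous gene counts per role; markers are
#'   spread round-robin across types.
#' @param marker_mean_in,marker_mean_out marker means in / out of the
#'   target type.
#' @param de_baseline_mean,de_fold DE baseline mean and fold change in
#'   target types.
#' @param ubiq_mean mean of ubiquitous genes.
#' @param dispersion negative-binomial size parameter (> 0; `Inf` for
#'   Poisson).
#' @param depth_factor_range length-2 positive range for per-cell depth
#'   factors.
#' @param n_classes optional number of classes grouping the types into
#'   a second, coarser hierarchy level.
#' @param seed integer seed; the same config and seed reproduce the
#'   dataset bit for bit.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_types = 4L, cells_per_type = 200L,
                              n_marker = 40L, n_de = 40L,
                              n_ubiquitous = 100L,
                              marker_mean_in = 10, marker_mean_out = 0.1,
                              de_baseline_mean = 1, de_fold = 4,
                              ubiq_mean = 2, dispersion = 1,
                              depth_factor_range = c(0.5, 2),
                              n_classes = NULL, seed = 1L) {
  cfg <- list(n_types = as.integer(n_types),
              cells_per_type = as.integer(cells_per_type),
              n_marker = as.integer(n_marker), n_de = as.integer(n_de),
              n_ubiquitous = as.integer(n_ubiquitous),
              marker_mean_in = marker_mean_in,
              marker_mean_out = marker_mean_out,
              de_baseline_mean = de_baseline_mean, de_fold = de_fold,
              ubiq_mean = ubiq_mean, dispersion = dispersion,
              depth_factor_range = as.numeric(depth_factor_range),
              n_classes = if (is.null(n_classes)) NULL
              else as.integer(n_classes),
              seed = as.integer(seed))
  if (cfg$n_types < 2L) stop2("n_types must be >= 2")
  if (cfg$cells_per_type < 10L) stop2("cells_per_type must be >= 10")
  if (any(c(cfg$n_marker, cfg$n_de, cfg$n_ubiquitous) < 0L))
    stop2("gene counts must be non-negative")
  if (cfg$n_marker + cfg$n_de + cfg$n_ubiquitous < 1L)
    stop2("at least one gene must be simulated")
  means <- c(cfg$marker_mean_in, cfg$marker_mean_out,
             cfg$de_baseline_mean, cfg$ubiq_mean)
  if (any(!is.finite(means)) || any(means <= 0))
    stop2("all means must be positive and finite")
  if (cfg$de_fold <= 0) stop2("de_fold must be positive")
  if (!(cfg$dispersion > 0)) stop2("dispersion must be positive")
  if (length(cfg$depth_factor_range) != 2L ||
      any(cfg$depth_factor_range <= 0) ||
      diff(cfg$depth_factor_range) < 0)
    stop2("depth_factor_range must be a positive increasing interval")
  if (!is.null(cfg$n_classes) &&
      (cfg$n_classes < 1L || cfg$n_classes > cfg$n_types))
    stop2("n_classes must be between 1 and n_types")
  structure(cfg, class = "simulation_config")
}

#' Simulate a labeled single-cell count dataset with planted roles
#'
#' Draws `counts(c, g) ~ NB(mean = depth(c) * mu(g, type(c)),
#' size = dispersion)` under the role-specific mean structure of
#' [simulation_config()]. Names are deterministic (`G0001...`,
#' `C0001...`, `T01...`), and identical seeds give identical output.
#'
#' @param config a [simulation_config()].
#' @return list of class `simulated_dataset`: `counts` (cells x genes
#'   sparse matrix), `annotation` (data.frame with `cell_id`, `type`
#'   and, when `n_classes` is set, `class`), `truth` (data.frame with
#'   `gene`, `role`, `target_types`, `mean_in`, `mean_out`), `config`.
#' @export
#' @examples
#' sim <- simulate_dataset(simulation_config(n_types = 2,
#'   cells_per_type = 20, n_marker = 2, n_de = 2, n_ubiquitous = 2))
#' dim(sim$counts)
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    n_types <- config$n_types
    n_cells <- n_types * config$cells_per_type
    types <- sprintf("T%02d", seq_len(n_types))
    cell_type <- rep(seq_len(n_types), each = config$cells_per_type)
    cell_ids <- sprintf("C%04d", seq_len(n_cells))
    n_genes <- config$n_marker + config$n_de + config$n_ubiquitous
    gene_ids <- sprintf("G%04d", seq_len(n_genes))
    role <- rep(c("marker", "de", "ubiquitous"),
                c(config$n_marker, config$n_de, config$n_ubiquitous))
    mu <- matrix(NA_real_, n_genes, n_types)
    targets <- vector("list", n_genes)
    if (config$n_marker > 0L) {
      tt <- rep_len(seq_len(n_types), config$n_marker)  # round-robin
      for (g in seq_len(config$n_marker)) {
        mu[g, ] <- config$marker_mean_out
        mu[g, tt[g]] <- config$marker_mean_in
        targets[[g]] <- tt[g]
      }
    }
    if (config$n_de > 0L) {
      max_targets <- min(3L, n_types - 1L)
      for (k in seq_len(config$n_de)) {
        g <- config$n_marker + k
        n_t <- sample.int(max_targets, 1L)
        tt <- sort(sample.int(n_types, n_t))
        mu[g, ] <- config$de_baseline_mean
        mu[g, tt] <- config$de_baseline_mean * config$de_fold
        targets[[g]] <- tt
      }
    }
    if (config$n_ubiquitous > 0L) {
      for (k in seq_len(config$n_ubiquitous)) {
        g <- config$n_marker + config$n_de + k
        mu[g, ] <- config$ubiq_mean
        targets[[g]] <- integer(0)
      }
    }
    rng <- log(config$depth_factor_range)
    depth <- exp(runif(n_cells, rng[1L], rng[2L]))
    counts <- matrix(0L, n_cells, n_genes,
                     dimnames = list(cell_ids, gene_ids))
    poisson <- is.infinite(config$dispersion)
    for (g in seq_len(n_genes)) {
      mu_cell <- depth * mu[g, cell_type]
      counts[, g] <- if (poisson) rpois(n_cells, mu_cell)
      else rnbinom(n_cells, size = config$dispersion, mu = mu_cell)
    }
    annotation <- data.frame(cell_id = cell_ids, type = types[cell_type],
                             stringsAsFactors = FALSE)
    if (!is.null(config$n_classes)) {
      class_of_type <- sprintf("CL%02d",
                               rep_len(seq_len(config$n_classes), n_types))
      annotation$class <- class_of_type[cell_type]
    }
    truth <- data.frame(
      gene = gene_ids, role = role,
      target_types = vapply(targets, function(t)
        paste(types[t], collapse = ","), character(1L)),
      mean_in = ifelse(role == "marker", config$marker_mean_in,
                       ifelse(role == "de",
                              config$de_baseline_mean * config$de_fold,
                              config$ubiq_mean)),
      mean_out = ifelse(role == "marker", config$marker_mean_out,
                        ifelse(role == "de", config$de_baseline_mean,
                               config$ubiq_mean)),
      stringsAsFactors = FALSE)
    structure(list(counts = expression_matrix(counts),
                   annotation = annotation, truth = truth,
                   config = config),
              class = "simulated_dataset")
  })
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("Simulated dataset:", nrow(x$counts), "cells x", ncol(x$counts),
      "genes,", x$config$n_types, "types (seed", x$config$seed, ")\n")
  print(table(x$truth$role))
  invisible(x)
}

#' Build gene sets with controlled role composition
#'
#' Assembles named gene sets from the simulation truth so downstream
#' comparisons have a known expected direction (e.g. a marker-rich set
#' versus a set of ubiquitous genes). Each scheme entry names the roles
#' to draw from and optionally a size `n` (default: all genes of those
#' roles).
#'
#' @param truth truth data.frame from [simulate_dataset()].
#' @param scheme named list; each element a list with `roles`
#'   (character subset of marker/de/ubiquitous) and optional `n`.
#' @param seed seed used when subsampling.
#' @return named list of character vectors of gene symbols.
#' @export
#' @examples
#' sim <- simulate_dataset(simulation_config(n_marker = 4, n_de = 2,
#'   n_ubiquitous = 4, cells_per_type = 10))
#' simulate_gene_sets(sim$truth,
#'   list(markers = list(roles = "marker"),
#'        background = list(roles = "ubiquitous", n = 3)))
simulate_gene_sets <- function(truth, scheme, seed = 1L) {
  stopifnot(is.data.frame(truth), nrow(truth) >= 1L)
  if (!is.list(scheme) || !length(scheme) || is.null(names(scheme)))
    stop2("scheme must be a non-empty named list")
  with_seed(seed, {
    out <- lapply(names(scheme), function(nm) {
      sp <- scheme[[nm]]
      roles <- sp$roles
      if (is.null(roles) ||
          !all(roles %in% c("marker", "de", "ubiquitous")))
        stop2("scheme entry '", nm, "' has invalid roles")
      pool <- truth$gene[truth$role %in% roles]
      n <- if (is.null(sp$n)) length(pool) else sp$n
      if (n < 1L || n > length(pool))
        stop2("scheme entry '", nm, "' requests ", n, " genes but only ",
              length(pool), " are available")
      if (n == length(pool)) pool else sort(sample(pool, n))
    })
    names(out) <- names(scheme)
    out
  })
}

#' Simulate a LOEUF constraint table for planted genes
#'
#' Draws one LOEUF value per gene from a role-specific log-normal
#' distribution. The defaults make marker genes the least constrained
#' (highest LOEUF) and ubiquitous genes the most constrained, so
#' [constraint_summary()] separates role-based sets. A `sdlog` of 0
#' gives a degenerate point distribution.
#'
#' @param truth truth data.frame from [simulate_dataset()].
#' @param association named list mapping each role to
#'   `c(meanlog, sdlog)` of the LOEUF log-normal.
#' @param seed seed for reproducibility.
#' @return data.frame with columns `gene` and `loeuf`.
#' @export
simulate_constraint_table <- function(truth,
                                      association = list(
                                        marker = c(log(0.9), 0.3),
                                        de = c(log(0.6), 0.3),
                                        ubiquitous = c(log(0.4), 0.3)),
                                      seed = 1L) {
  stopifnot(is.data.frame(truth))
  missing_roles <- setdiff(unique(truth$role), names(association))
  if (length(missing_roles))
    stop2("association missing role(s): ",
          paste(missing_roles, collapse = ", "))
  with_seed(seed, {
    loeuf <- numeric(nrow(truth))
    for (r in unique(truth$role)) {
      pars <- association[[r]]
      sel <- truth$role == r
      loeuf[sel] <- if (pars[2L] == 0) rep(exp(pars[1L]), sum(sel))
      else rlnorm(sum(sel), pars[1L], pars[2L])
    }
    data.frame(gene = truth$gene, loeuf = loeuf, stringsAsFactors = FALSE)
  })
}
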