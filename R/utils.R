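#' Normalize gene symbols
#'
#' Upper-cases and trims whitespace so symbols match case-insensitively
#' across count matrices, gene sets and constraint tables. Idempotent.
#'
#' @param x character vector of gene symbols.
#' @return character vector of normalized symbols.
#' @export
#' @examples
#' normalize_symbols(c(" Mog", "chd8"))
normalize_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards. `seed = NULL` leaves the
# global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Abort with a single-line diagnostic, no call.
stop2 <- function(...) stop(..., call. = FALSE)

# Write a data.frame as TSV, deterministically.
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
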