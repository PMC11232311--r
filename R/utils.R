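#' @keywords internal
"_PACKAGE"

## Shared low-level helpers: seeded evaluation and TSV I/O conventions used
## by every module (UTF-8, tab-separated, header row, no quoting).

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the random number generator seeded at `seed` and restores
#' the caller's RNG state afterwards, so seeded helpers do not perturb user
#' code.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Read a tab-separated table with a header row
#'
#' @param path File path.
#' @param ... Passed to [utils::read.delim()].
#' @return A data.frame.
#' @export
read_tsv_table <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, fileEncoding = "UTF-8",
                    na.strings = c("NA", ""), ...)
}

#' Write a tab-separated table with a header row
#'
#' @param x A data.frame.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8", na = "NA")
  invisible(path)
}

## competition ("min") ranking of a vector where larger values rank first
rank_desc_min <- function(x) {
  rank(-x, ties.method = "min")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
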