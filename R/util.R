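# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state, so
#' seeded package functions never disturb the user's random stream. With
#' `seed = NULL` the expression runs on the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Deterministic integer formatting for file output (no scientific notation).
fmt_int <- function(x) format(x, scientific = FALSE, trim = TRUE)

# Write a data frame as TSV with '#'-prefixed metadata header lines.
# `meta` is a named character vector; values must not contain newlines.
write_tsv_meta <- function(df, path, meta = character(0)) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(meta)) {
    writeLines(sprintf("# %s: %s", names(meta), as.character(meta)), con)
  }
  writeLines(paste(colnames(df), collapse = "\t"), con)
  if (nrow(df)) {
    cells <- vapply(df, function(col) {
      if (is.numeric(col) && !is.integer(col)) {
        format(col, scientific = FALSE, trim = TRUE, digits = 15)
      } else {
        as.character(col)
      }
    }, character(nrow(df)))
    if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
    writeLines(apply(cells, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}

# Short md5 of a serialized R object, for reproducibility metadata.
config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(deparse(x), collapse = "\n"), tf)
  unname(substr(tools::md5sum(tf), 1L, 12L))
}
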