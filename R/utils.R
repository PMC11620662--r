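#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

#' Evaluate an expression with an isolated, seeded RNG state
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the previous state on exit so that simulators never perturb the
#' session RNG stream.
#'
#' @param seed integer seed (mandatory).
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# stop() with a consistent prefix for input-format problems
format_error <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) format_error(...)
  invisible(TRUE)
}

# Deterministic TSV writer: UTF-8, LF endings, no quoting, no row names.
write_tsv_file <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(
    paste(colnames(df), collapse = "\t"),
    do.call(paste, c(lapply(df, function(col) {
      if (is.numeric(col)) format(col, trim = TRUE, scientific = FALSE, digits = 15) else as.character(col)
    }), sep = "\t"))
  )
  if (nrow(df) == 0L) lines <- lines[1L]
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

# md5 of a character scalar (via a temp file; tools::md5sum is file-based)
md5_of_string <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(x, tf, sep = "")
  unname(tools::md5sum(tf))
}
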