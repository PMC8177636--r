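# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cyclic index shift of rows
#' @keywords internal
row_shift <- function(m, by) {
  n <- nrow(m)
  idx <- ((seq_len(n) - 1 + by) %% n) + 1
  m[idx, , drop = FALSE]
}

#' Cyclic shift of a vector
#' @keywords internal
vec_shift <- function(v, by) {
  n <- length(v)
  v[((seq_len(n) - 1 + by) %% n) + 1]
}

#' Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's
#' RNG state afterwards. All stochastic code in the package funnels
#' through this so results are reproducible and side-effect free.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Format a numeric for lossless text round trip
#' @keywords internal
fmt_full <- function(x) sprintf("%.17g", x)

#' Deterministic CSV writer (fixed formatting, LF endings, no quoting)
#' @keywords internal
write_csv_det <- function(df, path, digits = 12) {
  fmt <- function(col) {
    if (is.numeric(col)) sprintf(paste0("%.", digits, "g"), col) else as.character(col)
  }
  cols <- lapply(df, fmt)
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' @keywords internal
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
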