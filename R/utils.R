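#' Read a square numeric matrix from delimited text
#'
#' Accepts whitespace- or comma-delimited plain text. A header row plus a
#' leading label column are auto-detected when the first field of the first
#' line is non-numeric and `labels = TRUE` is allowed.
#'
#' @param path file path.
#' @param labels if `TRUE`, attempt to read row/column labels from a header
#'   row and a first column of names.
#' @return a numeric matrix (with `dimnames` when labels were found).
#' @export
read_matrix_text <- function(path, labels = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  fields <- strsplit(trimws(first), if (sep == ",") "," else "[[:space:]]+")[[1]]
  has_header <- labels && is.na(suppressWarnings(as.numeric(fields[1])))
  if (has_header) {
    df <- read.table(path, sep = sep, header = TRUE, row.names = 1,
                     check.names = FALSE)
    m <- as.matrix(df)
  } else {
    m <- as.matrix(read.table(path, sep = sep, header = FALSE))
    dimnames(m) <- NULL
  }
  storage.mode(m) <- "double"
  m
}

#' Write a numeric matrix as delimited text
#'
#' Values are formatted with 9 significant digits, space separated, one matrix
#' row per line.
#'
#' @param m numeric matrix.
#' @param path output file path.
#' @export
write_matrix_text <- function(m, path) {
  txt <- apply(m, 1L, function(row)
    paste(formatC(row, digits = 9L, format = "g"), collapse = " "))
  writeLines(txt, path)
  invisible(path)
}

# strict upper-triangle vector, column-major order
upper_tri_vec <- function(m) m[upper.tri(m)]

# evaluate `expr` under a temporary RNG seed without touching the caller's
# RNG stream
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a finite numeric scalar")
  if (positive && x <= 0) stop("'", name, "' must be > 0")
  invisible(x)
}
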