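#' Read and write interaction matrices as delimited text
#'
#' The default dialect is labeled TSV: a header line of column (Y-set) species
#' labels, then one line per row (X-set) species starting with its label.
#' `labeled_csv` is the comma-separated equivalent; `headerless` is a bare
#' numeric table with no labels, for which synthetic labels `X1..`, `Y1..`
#' are generated. Rows are always the X set (e.g. plants), columns the Y set
#' (e.g. pollinators). `read_interaction_matrix(write_interaction_matrix(m))`
#' round-trips exactly, labels included.
#'
#' @param path File path.
#' @param dialect One of `"labeled_tsv"` (default), `"labeled_csv"`,
#'   `"headerless"`.
#' @return `read_interaction_matrix()` returns an [interaction_matrix()];
#'   `write_interaction_matrix()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write_interaction_matrix(matrix_nested_packed(3), f)
#' read_interaction_matrix(f)
#' @export
read_interaction_matrix <- function(path, dialect = c("labeled_tsv",
                                                      "labeled_csv",
                                                      "headerless")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  sep <- if (dialect == "labeled_csv") "," else "\t"
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop(sprintf("empty file: %s", path), call. = FALSE)
  fields <- strsplit(lines, sep, fixed = TRUE)
  if (length(unique(lengths(fields))) != 1) {
    bad <- which(lengths(fields) != lengths(fields)[1])[1]
    stop(sprintf("ragged table in %s: line %d has %d fields, expected %d",
                 path, bad, lengths(fields)[bad], lengths(fields)[1]),
         call. = FALSE)
  }
  if (dialect == "headerless") {
    row_labels <- NULL
    col_labels <- NULL
    body <- fields
  } else {
    col_labels <- fields[[1]][-1]
    body <- fields[-1]
    row_labels <- vapply(body, `[`, character(1), 1L)
    body <- lapply(body, `[`, -1L)
  }
  vals <- suppressWarnings(lapply(body, as.numeric))
  for (i in seq_along(vals)) {
    bad <- which(is.na(vals[[i]]))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric cell at data row %d, column %d of %s",
                   i, bad[1], path), call. = FALSE)
    }
    neg <- which(vals[[i]] < 0)
    if (length(neg) > 0) {
      stop(sprintf("negative cell at data row %d, column %d of %s",
                   i, neg[1], path), call. = FALSE)
    }
  }
  interaction_matrix(do.call(rbind, vals), row_labels = row_labels,
                     col_labels = col_labels)
}

#' @rdname read_interaction_matrix
#' @param mat An [interaction_matrix()] or coercible matrix.
#' @export
write_interaction_matrix <- function(mat, path, dialect = c("labeled_tsv",
                                                            "labeled_csv",
                                                            "headerless")) {
  mat <- as_interaction_matrix(mat)
  dialect <- match.arg(dialect)
  sep <- if (dialect == "labeled_csv") "," else "\t"
  body <- apply(unclass(mat), 1, function(r) {
    paste(as.character(r), collapse = sep)
  })
  lines <- if (dialect == "headerless") {
    body
  } else {
    c(paste(c("", colnames(mat)), collapse = sep),
      paste(rownames(mat), body, sep = sep))
  }
  writeLines(lines, path)
  invisible(path)
}
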