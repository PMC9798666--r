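#' Read a delimited matrix with row and column identifiers
#'
#' Parses the tab-delimited matrix dialect used by the public interaction
#' benchmarks: first row holds column identifiers, first column holds row
#' identifiers, every other cell is numeric. The public files store targets in
#' rows; `orientation = "targets-in-rows"` (the default for
#' [read_interactions]) transposes on load so that the returned matrix is
#' always drugs-by-targets.
#'
#' @param path File path.
#' @param orientation Either `"drugs-in-rows"` or `"targets-in-rows"`; with
#'   the latter the parsed matrix is transposed.
#' @param delim Cell delimiter; tab by default, `","` accepted.
#' @return A list with `row_ids`, `col_ids` and `matrix` (after any
#'   transposition: `row_ids` index the matrix rows).
#' @details Ragged rows and non-numeric cells raise a format error naming the
#'   offending line; duplicated identifiers raise a validation error.
#' @export
read_matrix_file <- function(path,
                             orientation = c("drugs-in-rows", "targets-in-rows"),
                             delim = "\t") {
  orientation <- match.arg(orientation)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    abort(sprintf("'%s': need a header line and at least one data line", path),
          class = "grmfc_format_error")
  }
  cells <- strsplit(lines, delim, fixed = TRUE)
  header <- cells[[1L]]
  # header may or may not carry a leading corner cell above the id column
  body_width <- length(cells[[2L]])
  col_ids <- if (length(header) == body_width) header[-1L] else header
  n_col <- length(col_ids)
  body <- cells[-1L]
  widths <- lengths(body)
  if (any(widths != n_col + 1L)) {
    bad <- which(widths != n_col + 1L)[1L]
    abort(sprintf("'%s': ragged row at line %d (%d cells, expected %d)",
                  path, bad + 1L, widths[bad], n_col + 1L),
          class = "grmfc_format_error")
  }
  row_ids <- vapply(body, `[[`, character(1), 1L)
  values <- suppressWarnings(
    vapply(body, function(r) as.numeric(r[-1L]), numeric(n_col))
  )
  values <- matrix(values, nrow = n_col)  # columns of vapply = file rows
  if (anyNA(values)) {
    bad <- which(apply(is.na(values), 2L, any))[1L]
    abort(sprintf("'%s': non-numeric cell at line %d", path, bad + 1L),
          class = "grmfc_format_error")
  }
  if (anyDuplicated(row_ids) || anyDuplicated(col_ids)) {
    abort(sprintf("'%s': duplicated identifiers", path),
          class = "grmfc_validation_error")
  }
  mat <- t(values)
  dimnames(mat) <- list(row_ids, col_ids)
  if (orientation == "targets-in-rows") {
    mat <- t(mat)
    tmp <- row_ids; row_ids <- col_ids; col_ids <- tmp
  }
  list(row_ids = row_ids, col_ids = col_ids, matrix = mat)
}

#' Write a matrix in the delimited identifier format
#'
#' Inverse of [read_matrix_file]: writes a header of column identifiers, then
#' one line per row with its identifier. Numbers are written with full
#' precision so a read/write/read round trip is exact.
#'
#' @param mat Matrix with dimnames (or supply `row_ids`/`col_ids`).
#' @param path Output path.
#' @param row_ids,col_ids Identifier vectors; default to the dimnames.
#' @param delim Cell delimiter.
#' @return `path`, invisibly.
#' @export
write_matrix_file <- function(mat, path, row_ids = rownames(mat),
                              col_ids = colnames(mat), delim = "\t") {
  stopifnot(!is.null(row_ids), !is.null(col_ids))
  header <- paste(c("", col_ids), collapse = delim)
  rows <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(row_ids[i], format(mat[i, ], digits = 17, trim = TRUE,
                               scientific = FALSE)),
          collapse = delim)
  }, character(1))
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read an interaction matrix file into an `interaction_data` object
#'
#' @inheritParams read_matrix_file
#' @param orientation The public benchmark files store targets in rows, the
#'   package default.
#' @return An [interaction_data] object (drugs in rows).
#' @export
read_interactions <- function(path, orientation = "targets-in-rows",
                              delim = "\t") {
  parsed <- read_matrix_file(path, orientation, delim)
  interaction_data(parsed$matrix, parsed$row_ids, parsed$col_ids)
}

#' Read a similarity matrix file
#'
#' @inheritParams read_matrix_file
#' @return A [similarity_matrix] object.
#' @export
read_similarity <- function(path, delim = "\t") {
  parsed <- read_matrix_file(path, "drugs-in-rows", delim)
  similarity_matrix(parsed$matrix, parsed$row_ids)
}

#' Write ranked predictions as a three-column table
#'
#' @param predictions A tibble with columns `drug_id`, `target_id`, `score`
#'   (as produced by [tidy.grmfc_fit]).
#' @param path Output path.
#' @param delim Delimiter.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path, delim = "\t") {
  stopifnot(all(c("drug_id", "target_id", "score") %in% names(predictions)))
  predictions <- dplyr::arrange(predictions, dplyr::desc(.data$score))
  utils::write.table(predictions[, c("drug_id", "target_id", "score")],
                     path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}
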