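#' Validate a binary mutation matrix
#'
#' A mutation matrix is an integer matrix with samples in rows and genes in
#' columns, entries in \{0, 1\}, and unique non-empty row and column names.
#'
#' @param A matrix to validate.
#' @return `A` as an integer matrix (stops on violation).
#' @export
validate_mutation_matrix <- function(A) {
  if (!is.matrix(A) || !is.numeric(A)) {
    stop_f("mutation matrix must be a numeric matrix")
  }
  if (nrow(A) < 1L) stop_f("mutation matrix has no samples")
  if (ncol(A) < 1L) stop_f("mutation matrix has no genes")
  if (is.null(rownames(A)) || is.null(colnames(A))) {
    stop_f("mutation matrix must have sample (row) and gene (column) names")
  }
  if (anyDuplicated(rownames(A))) {
    stop_f("duplicate sample ids: %s",
           paste(unique(rownames(A)[duplicated(rownames(A))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(A))) {
    stop_f("duplicate gene ids: %s",
           paste(unique(colnames(A)[duplicated(colnames(A))]), collapse = ", "))
  }
  bad <- which(is.na(A) | !(A == 0 | A == 1))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(A)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(A)) + 1L
    stop_f("non-binary value '%s' at sample '%s', gene '%s'",
           format(A[bad[1]]), rownames(A)[i], colnames(A)[j])
  }
  storage.mode(A) <- "integer"
  A
}

validate_expression_matrix <- function(E) {
  if (!is.matrix(E) || !is.numeric(E)) {
    stop_f("expression matrix must be a numeric matrix")
  }
  if (nrow(E) < 1L || ncol(E) < 1L) stop_f("expression matrix is empty")
  if (is.null(rownames(E)) || is.null(colnames(E))) {
    stop_f("expression matrix must have sample (row) and gene (column) names")
  }
  if (anyDuplicated(rownames(E)) || anyDuplicated(colnames(E))) {
    stop_f("expression matrix has duplicate sample or gene ids")
  }
  storage.mode(E) <- "double"
  E
}

read_matrix_tsv <- function(path, transpose) {
  if (!file.exists(path)) stop_f("file not found: %s", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2L) stop_f("%s: expected sample-id column plus >= 1 gene column", path)
  if (nrow(raw) == 0L) stop_f("%s: no samples (header-only file)", path)
  ids <- raw[[1]]
  body <- as.matrix(raw[, -1, drop = FALSE])
  out <- matrix(NA_real_, nrow(body), ncol(body),
                dimnames = list(ids, colnames(raw)[-1]))
  suppressWarnings(out[] <- as.numeric(body))
  # empty strings / "NA" become NA; caller decides whether that is allowed
  attr(out, "raw_cells") <- body
  if (transpose) {
    rc <- attr(out, "raw_cells")
    out <- t(out[, , drop = FALSE])
    attr(out, "raw_cells") <- t(rc)
  }
  out
}

#' Read a binary mutation matrix from TSV
#'
#' The expected layout is a tab-separated file whose header row holds gene
#' identifiers, whose first column holds sample identifiers, and whose body is
#' 0/1.  `transpose = TRUE` accepts the genes-in-rows orientation instead.
#'
#' @param path path to the TSV file.
#' @param transpose logical; set `TRUE` if the file stores genes in rows.
#' @return an integer samples-by-genes matrix with dimnames.
#' @seealso [write_mutation_matrix()], [read_expression_matrix()]
#' @export
read_mutation_matrix <- function(path, transpose = FALSE) {
  out <- read_matrix_tsv(path, transpose)
  raw <- attr(out, "raw_cells")
  attr(out, "raw_cells") <- NULL
  bad <- which(is.na(out) | !(out == 0 | out == 1))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(out)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(out)) + 1L
    stop_f("%s: non-binary cell '%s' at sample '%s', gene '%s'",
           path, raw[bad[1]], rownames(out)[i], colnames(out)[j])
  }
  validate_mutation_matrix(out)
}

#' Read a gene-expression matrix from TSV
#'
#' Same layout as [read_mutation_matrix()] but real-valued; empty cells or
#' `NA` are read as missing values.
#'
#' @inheritParams read_mutation_matrix
#' @return a numeric samples-by-genes matrix (may contain `NA`).
#' @export
read_expression_matrix <- function(path, transpose = FALSE) {
  out <- read_matrix_tsv(path, transpose)
  raw <- attr(out, "raw_cells")
  attr(out, "raw_cells") <- NULL
  missing_cell <- is.na(raw) | raw == "" | toupper(raw) == "NA"
  unparsed <- is.na(out) & !missing_cell
  if (any(unparsed)) {
    bad <- which(unparsed)[1]
    i <- ((bad - 1L) %% nrow(out)) + 1L
    j <- ((bad - 1L) %/% nrow(out)) + 1L
    stop_f("%s: non-numeric cell '%s' at sample '%s', gene '%s'",
           path, raw[bad], rownames(out)[i], colnames(out)[j])
  }
  validate_expression_matrix(out)
}

write_matrix_tsv <- function(x, path) {
  df <- data.frame(sample = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a mutation or expression matrix as TSV
#'
#' Writes the samples-by-genes layout read back by [read_mutation_matrix()] /
#' [read_expression_matrix()]; the round trip is exact for valid matrices.
#'
#' @param A matrix with sample row names and gene column names.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mutation_matrix <- function(A, path) {
  A <- validate_mutation_matrix(A)
  write_matrix_tsv(A, path)
}

#' @rdname write_mutation_matrix
#' @param E expression matrix.
#' @export
write_expression_matrix <- function(E, path) {
  E <- validate_expression_matrix(E)
  write_matrix_tsv(E, path)
}
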