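#' Collapse genes with identical mutation profiles into metagenes
#'
#' Genes mutated in exactly the same set of samples are indistinguishable to
#' the coverage/exclusivity weight and often arise from co-amplified loci
#' (e.g. neighbouring genes on one amplicon).  They are merged into a single
#' "metagene" column whose identifier joins the member ids with `"+"` in
#' their input column order.  Genes with no mutations at all are never merged
#' (merging uncovered genes would fabricate spurious metagenes); they are kept
#' as-is and reported in `zero_coverage`.
#'
#' @param A binary mutation matrix (samples x genes).
#' @return a list of class `metagene_collapse` with elements
#'   \item{mutations}{the collapsed mutation matrix, columns ordered by first
#'     member appearance;}
#'   \item{mapping}{data.frame with columns `metagene_id`, `member_id`, one
#'     row per original gene;}
#'   \item{zero_coverage}{character vector of gene ids with no mutations.}
#' @examples
#' A <- matrix(c(1,0,1,0, 1,0,1,0, 0,1,0,0), nrow = 4,
#'             dimnames = list(paste0("s", 1:4), c("geneA", "geneB", "geneC")))
#' collapse_metagenes(A)$mapping
#' @export
collapse_metagenes <- function(A) {
  A <- validate_mutation_matrix(A)
  n <- ncol(A)
  key <- vapply(seq_len(n), function(j) paste(which(A[, j] == 1L), collapse = ","),
                character(1))
  zero <- key == ""
  # all-zero columns get unique keys so they never merge
  key[zero] <- paste0("zero:", which(zero))
  first <- !duplicated(key)
  groups <- split(seq_len(n), match(key, key[first]))
  ord <- order(vapply(groups, `[`, integer(1), 1L))
  groups <- groups[ord]
  ids <- unname(vapply(groups, function(g) paste(colnames(A)[g], collapse = "+"),
                       character(1)))
  out <- A[, vapply(groups, `[`, integer(1), 1L), drop = FALSE]
  colnames(out) <- ids
  mapping <- data.frame(
    metagene_id = rep(ids, lengths(groups)),
    member_id = colnames(A)[unlist(groups, use.names = FALSE)],
    stringsAsFactors = FALSE
  )
  structure(list(mutations = out, mapping = mapping,
                 zero_coverage = colnames(A)[zero]),
            class = "metagene_collapse")
}

#' @export
print.metagene_collapse <- function(x, ...) {
  merged <- sum(table(x$mapping$metagene_id) > 1L)
  cat(sprintf("Metagene collapse: %d genes -> %d columns (%d metagenes merged, %d uncovered genes)\n",
              nrow(x$mapping), ncol(x$mutations), merged,
              length(x$zero_coverage)))
  invisible(x)
}

#' Write a metagene mapping as two-column TSV
#'
#' @param x a `metagene_collapse` object.
#' @param path output path; columns `metagene_id`, `member_id`.
#' @return `path`, invisibly.
#' @export
write_metagene_mapping <- function(x, path) {
  stopifnot(inherits(x, "metagene_collapse"))
  utils::write.table(x$mapping, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Align a mutation and an expression matrix
#'
#' Restricts both matrices to their shared samples and shared genes, in the
#' mutation matrix's order, so that an expression submatrix can be looked up
#' for any gene set scored on the mutation matrix.
#'
#' @param A binary mutation matrix.
#' @param E expression matrix.
#' @return list with elements `mutations`, `expression` (both restricted to
#'   the common ids) and `dropped` (list of the sample/gene ids removed from
#'   each input).
#' @export
align_matrices <- function(A, E) {
  A <- validate_mutation_matrix(A)
  E <- validate_expression_matrix(E)
  samples <- intersect(rownames(A), rownames(E))
  genes <- intersect(colnames(A), colnames(E))
  if (length(samples) == 0L) stop_f("no samples in common between the matrices")
  if (length(genes) == 0L) stop_f("no genes in common between the matrices")
  list(
    mutations = A[samples, genes, drop = FALSE],
    expression = E[samples, genes, drop = FALSE],
    dropped = list(
      mutation_samples = setdiff(rownames(A), samples),
      mutation_genes = setdiff(colnames(A), genes),
      expression_samples = setdiff(rownames(E), samples),
      expression_genes = setdiff(colnames(E), genes)
    )
  )
}
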