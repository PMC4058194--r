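resolve_genes <- function(A, genes, allow_empty = FALSE) {
  genes <- as.character(genes)
  if (!allow_empty && length(genes) == 0L) {
    stop_f("the gene set is empty; scores are defined for k >= 1")
  }
  if (anyDuplicated(genes)) {
    stop_f("duplicate genes in set: %s",
           paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  idx <- match(genes, colnames(A))
  if (anyNA(idx)) {
    stop_f("unknown gene id(s): %s", paste(genes[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Coverage of a gene set
#'
#' The coverage Gamma(M) of a gene set M is the set of samples carrying at
#' least one mutation in a member of M.
#'
#' @param A binary mutation matrix (samples x genes).
#' @param genes character vector of gene ids in `A`.
#' @return character vector of covered sample ids.
#' @export
coverage_set <- function(A, genes) {
  A <- validate_mutation_matrix(A)
  idx <- resolve_genes(A, genes)
  rownames(A)[rowSums(A[, idx, drop = FALSE]) > 0L]
}

#' Coverage/exclusivity weight of a gene set
#'
#' Computes the maximum-weight-submatrix objective
#' `W(M) = |Gamma(M)| - omega(M) = 2|Gamma(M)| - sum_g |Gamma(g)|`,
#' where the overlap `omega(M) = sum_g |Gamma(g)| - |Gamma(M)|` counts
#' redundant co-occurring mutations within the set.  High weight means the
#' set covers many samples with near-mutually-exclusive mutations; a set of
#' pairwise column-disjoint genes attains `W(M) = |Gamma(M)|`.
#'
#' @inheritParams coverage_set
#' @return an object of class `pathway_score`: a list with integer fields
#'   `coverage` (|Gamma(M)|), `coverage_sum` (sum of per-gene coverages),
#'   `overlap` (omega(M)) and `weight` (W(M)), plus `genes` and `k`.
#' @examples
#' A <- matrix(0L, 4, 4, dimnames = list(paste0("s", 1:4), paste0("g", 1:4)))
#' A["s1", "g1"] <- A["s2", "g1"] <- A["s3", "g2"] <- A["s3", "g3"] <- A["s4", "g3"] <- 1L
#' pathway_weight(A, c("g1", "g3"))  # disjoint columns: W = coverage = 4
#' @export
pathway_weight <- function(A, genes) {
  A <- validate_mutation_matrix(A)
  idx <- resolve_genes(A, genes)
  per_gene <- colSums(A[, idx, drop = FALSE])
  cov <- sum(rowSums(A[, idx, drop = FALSE]) > 0L)
  new_pathway_score(
    genes = colnames(A)[idx],
    coverage = as.integer(cov),
    coverage_sum = as.integer(sum(per_gene)),
    samples = coverage_set(A, genes)
  )
}

new_pathway_score <- function(genes, coverage, coverage_sum, samples = NULL,
                              expression_term = NULL, lambda = NULL) {
  weight <- 2L * coverage - coverage_sum
  score <- if (!is.null(expression_term)) weight + lambda * expression_term
  structure(list(
    genes = genes, k = length(genes),
    coverage = coverage, coverage_sum = coverage_sum,
    overlap = coverage_sum - coverage, weight = weight,
    expression_term = expression_term, lambda = lambda,
    score = score %||% weight, samples = samples
  ), class = "pathway_score")
}

#' @export
print.pathway_score <- function(x, ...) {
  cat(sprintf("Gene set (k = %d): %s\n", x$k, paste(x$genes, collapse = ", ")))
  cat(sprintf("  coverage |Gamma(M)| = %d, overlap omega(M) = %d, weight W(M) = %d\n",
              x$coverage, x$overlap, x$weight))
  if (!is.null(x$expression_term)) {
    cat(sprintf("  expression coherence R(E_M) = %.4f, lambda = %g, F_ME = %.4f\n",
                x$expression_term, x$lambda, x$score))
  }
  invisible(x)
}

#' Expression coherence of a gene set
#'
#' The integrative model's expression term
#' `R(E_M) = sum_{j1 != j2} |pcc(x_j1, x_j2)| / (k(k-1)/2)` is the mean
#' absolute Pearson correlation over all unordered pairs of member genes'
#' expression profiles; it lies in \[0, 1\] and is large when the set's genes
#' are co-regulated, as genes of one pathway tend to be.
#'
#' Correlations use pairwise-complete observations.  A pair with fewer than 3
#' complete observations, or with zero variance in either profile, has no
#' defined correlation: by default this is an error; `zero_variance = "zero"`
#' scores such pairs as |pcc| = 0 instead.
#'
#' @param E expression matrix (samples x genes).
#' @param genes character vector of k >= 2 gene ids in `E`.
#' @param zero_variance `"error"` (default) or `"zero"`.
#' @return a single number in \[0, 1\].
#' @export
expression_concordance <- function(E, genes, zero_variance = c("error", "zero")) {
  E <- validate_expression_matrix(E)
  zero_variance <- match.arg(zero_variance)
  idx <- resolve_genes(E, genes)
  k <- length(idx)
  if (k < 2L) stop_f("expression coherence needs k >= 2 genes (got %d)", k)
  X <- E[, idx, drop = FALSE]
  obs <- !is.na(X)
  n_pair <- crossprod(obs)               # complete observations per pair
  cm <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  pairs <- which(upper.tri(cm), arr.ind = TRUE)
  vals <- abs(cm[pairs])
  undefined <- is.na(vals) | n_pair[pairs] < 3L
  if (any(undefined)) {
    if (zero_variance == "error") {
      b <- which(undefined)[1]
      stop_f("correlation undefined for gene pair (%s, %s): zero variance or < 3 complete observations",
             colnames(X)[pairs[b, 1]], colnames(X)[pairs[b, 2]])
    }
    vals[undefined] <- 0
  }
  r <- mean(vals)
  # guard against fp drift just past 1
  min(max(r, 0), 1)
}

#' Integrative mutation + expression score
#'
#' Scores a gene set by `F_ME = W(M) + lambda * R(E_M)`: the
#' coverage/exclusivity weight of its mutations plus a lambda-weighted
#' expression-coherence bonus.  With `lambda = 1` the expression term breaks
#' ties between sets of equal mutation weight; larger lambda (the reference
#' settings are 1 and 10) favours strongly co-expressed sets outright.
#'
#' @param A binary mutation matrix, aligned with `E` (see [align_matrices()]).
#' @param E expression matrix over the same samples and genes.
#' @param genes character vector of k >= 2 gene ids.
#' @param lambda non-negative coefficient of the expression term.
#' @param zero_variance passed to [expression_concordance()].
#' @return a `pathway_score` whose `score` field holds F_ME.
#' @export
integrative_score <- function(A, E, genes, lambda = 1,
                              zero_variance = c("error", "zero")) {
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) || lambda < 0) {
    stop_f("`lambda` must be a single non-negative number")
  }
  w <- pathway_weight(A, genes)
  r <- expression_concordance(E, genes, zero_variance)
  new_pathway_score(
    genes = w$genes, coverage = w$coverage, coverage_sum = w$coverage_sum,
    samples = w$samples, expression_term = r, lambda = lambda
  )
}
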