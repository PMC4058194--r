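# Toy cohort used throughout: 4 samples x 4 genes.
#   s1: g1        s2: g1        s3: g2, g3     s4: g3
# g1 and g3 are column-disjoint and together cover every sample (W = 4);
# g2 and g3 co-occur in s3; g4 is never mutated.
toy_matrix <- function() {
  A <- matrix(0L, 4, 4, dimnames = list(paste0("s", 1:4), paste0("g", 1:4)))
  A["s1", "g1"] <- 1L
  A["s2", "g1"] <- 1L
  A["s3", "g2"] <- 1L
  A["s3", "g3"] <- 1L
  A["s4", "g3"] <- 1L
  A
}

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

random_mutation_matrix <- function(m, n, p = 0.2) {
  A <- matrix(as.integer(stats::runif(m * n) < p), m, n,
              dimnames = list(paste0("s", seq_len(m)), paste0("g", seq_len(n))))
  A
}

# Independent brute-force oracle for the maximum weight submatrix problem,
# deliberately built on set operations over sample-id lists rather than the
# package's column arithmetic.
brute_force_weight <- function(A, genes) {
  gammas <- lapply(genes, function(g) rownames(A)[A[, g] == 1L])
  covered <- unique(unlist(gammas))
  2L * length(covered) - sum(lengths(gammas))
}

brute_force_best <- function(A, k) {
  combos <- utils::combn(colnames(A), k, simplify = FALSE)
  weights <- vapply(combos, function(gs) brute_force_weight(A, gs), integer(1))
  best <- which(weights == max(weights))
  # lexicographically smallest sorted tuple among ties
  keys <- vapply(best, function(i) paste(sort(combos[[i]]), collapse = "\r"),
                 character(1))
  list(weight = max(weights), genes = sort(combos[[best[order(keys)[1]]]]))
}

# Textbook-formula Pearson correlation, independent of stats::cor.
naive_pcc <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
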