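test_that("coverage is the union of mutated-sample sets", {
  A <- toy_matrix()
  expect_identical(coverage_set(A, "g1"), c("s1", "s2"))
  expect_identical(coverage_set(A, c("g1", "g3")), paste0("s", 1:4))
  expect_identical(coverage_set(A, "g4"), character(0))
  expect_error(coverage_set(A, "g9"), "g9")
})

test_that("weight matches hand-enumerated values on the toy cohort", {
  A <- toy_matrix()
  w1 <- pathway_weight(A, "g1")
  expect_identical(w1$coverage, 2L)
  expect_identical(w1$coverage_sum, 2L)
  expect_identical(w1$weight, 2L)
  w23 <- pathway_weight(A, c("g2", "g3"))
  expect_identical(w23$coverage, 2L)
  expect_identical(w23$overlap, 1L)
  expect_identical(w23$weight, 1L)
  w13 <- pathway_weight(A, c("g1", "g3"))
  expect_identical(w13$coverage, 4L)
  expect_identical(w13$weight, 4L)  # disjoint columns: W = coverage
  expect_error(pathway_weight(A, character(0)), "empty")
  expect_error(pathway_weight(A, c("g1", "g1")), "duplicate")
})

test_that("the two printed forms of the weight agree on random matrices", {
  set.seed(11)
  for (i in 1:50) {
    A <- random_mutation_matrix(sample(4:15, 1), sample(3:12, 1), p = 0.3)
    k <- sample.int(min(4L, ncol(A)), 1)
    genes <- sample(colnames(A), k)
    sc <- pathway_weight(A, genes)
    # |Gamma(M)| - omega(M) == 2|Gamma(M)| - sum_g |Gamma(g)|
    expect_identical(sc$coverage - sc$overlap, 2L * sc$coverage - sc$coverage_sum)
    expect_identical(sc$weight, sc$coverage - sc$overlap)
    expect_gte(sc$overlap, 0L)
    # member order and sample-row permutation leave the weight unchanged
    expect_identical(pathway_weight(A, rev(genes))$weight, sc$weight)
    perm <- sample(nrow(A))
    expect_identical(pathway_weight(A[perm, , drop = FALSE], genes)$weight,
                     sc$weight)
    expect_identical(sc$weight, brute_force_weight(A, genes))
  }
})

test_that("adding an overlapping mutation decreases the weight by one", {
  A <- toy_matrix()
  base <- pathway_weight(A, c("g1", "g3"))$weight
  B <- A
  B["s1", "g3"] <- 1L  # s1 already covered via g1
  expect_identical(pathway_weight(B, c("g1", "g3"))$weight, base - 1L)
})

test_that("expression coherence averages absolute pairwise correlations", {
  E <- cbind(x1 = c(1, 2, 3), x2 = c(2, 4, 6), x3 = c(3, 2, 1))
  rownames(E) <- paste0("s", 1:3)
  expect_equal(expression_concordance(E, c("x1", "x2")), 1)
  # anti-correlation scores identically: the sign is discarded
  expect_equal(expression_concordance(E, c("x1", "x3")), 1)

  # three genes with pairwise |pcc| of 1, 0.5 and 0 -> mean 0.5
  set.seed(3)
  n <- 400
  a <- rnorm(n)
  b <- 0.5 * a + sqrt(1 - 0.25) * rnorm(n)   # |pcc| ~ 0.5 with a
  E2 <- cbind(ga = a, gb = b, gc = rnorm(n))
  rownames(E2) <- paste0("s", seq_len(n))
  expected <- mean(abs(c(naive_pcc(E2[, 1], E2[, 2]),
                         naive_pcc(E2[, 1], E2[, 3]),
                         naive_pcc(E2[, 2], E2[, 3]))))
  expect_equal(expression_concordance(E2, c("ga", "gb", "gc")), expected,
               tolerance = 1e-12)
  expect_true(expression_concordance(E2, c("ga", "gb", "gc")) >= 0)
  expect_true(expression_concordance(E2, c("ga", "gb", "gc")) <= 1)
})

test_that("degenerate correlation pairs follow the configured policy", {
  E <- cbind(flat = c(1, 1, 1, 1), x = c(1, 2, 3, 4), y = c(4, 3, 2, 1))
  rownames(E) <- paste0("s", 1:4)
  expect_error(expression_concordance(E, c("flat", "x")), "flat")
  expect_equal(expression_concordance(E, c("flat", "x"), zero_variance = "zero"), 0)
  expect_equal(expression_concordance(E, c("flat", "x", "y"), zero_variance = "zero"),
               1 / 3)  # only (x, y) contributes |pcc| = 1 of the 3 pairs
  # fewer than 3 complete observations in a pair is undefined
  E2 <- cbind(a = c(1, 2, NA, NA), b = c(1, NA, 2, 3))
  rownames(E2) <- paste0("s", 1:4)
  expect_error(expression_concordance(E2, c("a", "b")), "complete")
  expect_error(expression_concordance(E, "x"), "k >= 2")
})

test_that("coherence is invariant to affine rescaling of a column", {
  set.seed(9)
  E <- matrix(rnorm(60), 20, 3, dimnames = list(paste0("s", 1:20), c("a", "b", "c")))
  base <- expression_concordance(E, c("a", "b", "c"))
  E[, "b"] <- 5 - 3.7 * E[, "b"]
  expect_equal(expression_concordance(E, c("a", "b", "c")), base,
               tolerance = 1e-12)
})

test_that("the integrative score composes weight and coherence", {
  A <- toy_matrix()
  E <- cbind(g1 = c(1, 2, 3, 4), g2 = rnorm(4), g3 = c(2, 4, 6, 8),
             g4 = rnorm(4))
  rownames(E) <- rownames(A)
  # lambda = 0 reduces exactly to the mutation weight
  s0 <- integrative_score(A, E, c("g1", "g3"), lambda = 0)
  expect_identical(s0$score, 4)
  # W = 4 and perfectly collinear profiles (R = 1): F = W + lambda
  s1 <- integrative_score(A, E, c("g1", "g3"), lambda = 1)
  expect_equal(s1$expression_term, 1)
  expect_equal(s1$score, 5)
  s10 <- integrative_score(A, E, c("g1", "g3"), lambda = 10)
  expect_equal(s10$score, 14)
  expect_error(integrative_score(A, E, c("g1", "g3"), lambda = -1),
               "non-negative")
  # monotone non-decreasing in lambda when R > 0
  expect_true(s10$score >= s1$score && s1$score >= s0$score)
})
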