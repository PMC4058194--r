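test_that("simulation specs validate their parameters", {
  spec <- simulation_spec(seed = 1)
  expect_equal(spec$coverage_probs, 1 - (1:5) * 0.05)
  expect_error(simulation_spec(n_genes = 20, n_pathways = 5, set_size = 5),
               "exceeds n_genes")
  expect_error(simulation_spec(delta = 0.25, n_pathways = 5), "positive")
  expect_error(simulation_spec(delta = 0), "delta")
  expect_error(simulation_spec(p0 = 1.2), "p0")
})

test_that("identical seeds give bit-identical datasets", {
  spec <- simulation_spec(n_genes = 60, n_samples = 80, n_pathways = 2,
                          set_size = 3)
  d1 <- simulate_mutations(spec, seed = 42)
  d2 <- simulate_mutations(spec, seed = 42)
  expect_identical(d1$mutations, d2$mutations)
  expect_identical(d1$truth, d2$truth)
  d3 <- simulate_mutations(spec, seed = 43)
  expect_false(identical(d1$mutations, d3$mutations))
})

test_that("implanted sets are disjoint, binary and of the requested size", {
  d <- simulate_mutations(simulation_spec(n_genes = 80, n_samples = 100,
                                          n_pathways = 3, set_size = 4),
                          seed = 9)
  expect_true(all(d$mutations %in% c(0L, 1L)))
  expect_identical(length(d$truth), 3L)
  expect_true(all(lengths(d$truth) == 4L))
  expect_identical(anyDuplicated(unlist(d$truth)), 0L)
  expect_true(all(unlist(d$truth) %in% colnames(d$mutations)))
})

test_that("zero leak and zero background give perfectly exclusive pathways", {
  spec <- simulation_spec(n_genes = 40, n_samples = 300, n_pathways = 3,
                          set_size = 4, p0 = 0, background_rate = 0,
                          background = "fixed")
  d <- simulate_mutations(spec, seed = 4)
  for (genes in d$truth) {
    sc <- pathway_weight(d$mutations, genes)
    expect_identical(sc$overlap, 0L)          # pairwise disjoint columns
    expect_identical(sc$weight, sc$coverage)  # W = |Gamma(M)| exactly
  }
  # passengers never mutate at background rate zero
  passengers <- setdiff(colnames(d$mutations), unlist(d$truth))
  expect_identical(sum(d$mutations[, passengers]), 0L)
})

test_that("observed pathway coverage matches its binomial expectation", {
  spec <- simulation_spec(n_genes = 30, n_samples = 10000, n_pathways = 5,
                          set_size = 5, background_rate = 0,
                          background = "fixed")
  d <- simulate_mutations(spec, seed = 77)
  m <- spec$n_samples
  for (i in seq_along(d$truth)) {
    p <- spec$coverage_probs[i]
    observed <- mean(rowSums(d$mutations[, d$truth[[i]], drop = FALSE]) > 0)
    se <- sqrt(p * (1 - p) / m)
    expect_lt(abs(observed - p), 3 * se + 1e-12)
  }
})

test_that("the leak step only fires in covered rows unless told otherwise", {
  spec <- simulation_spec(n_genes = 20, n_samples = 2000, n_pathways = 1,
                          set_size = 5, delta = 0.5, p0 = 0.5,
                          background_rate = 0, background = "fixed")
  d <- simulate_mutations(spec, seed = 3)
  # conditional leak: a row is either empty in M_1 or has >= 1 mutation from
  # the coverage event; rows with exactly one mutation dominate at p_i = 0.5
  counts <- rowSums(d$mutations[, d$truth[[1]]])
  expect_lt(abs(mean(counts > 0) - 0.5), 3 * sqrt(0.25 / 2000))
  # unconditional leak mutates uncovered rows too, raising apparent coverage
  spec_u <- simulation_spec(n_genes = 20, n_samples = 2000, n_pathways = 1,
                            set_size = 5, delta = 0.5, p0 = 0.5,
                            background_rate = 0, background = "fixed",
                            unconditional_leak = TRUE)
  du <- simulate_mutations(spec_u, seed = 3)
  expect_gt(mean(rowSums(du$mutations[, du$truth[[1]]]) > 0), 0.8)
})

test_that("implanted sets outscore random same-size sets", {
  set.seed(55)
  wins <- 0L
  for (r in 1:20) {
    d <- simulate_mutations(simulation_spec(n_genes = 100, n_samples = 200,
                                            n_pathways = 2, set_size = 4),
                            seed = 500 + r)
    truth_w <- mean(vapply(d$truth,
                           function(g) pathway_weight(d$mutations, g)$weight,
                           integer(1)))
    rand_w <- mean(replicate(5, {
      pathway_weight(d$mutations, sample(colnames(d$mutations), 4))$weight
    }))
    if (truth_w > rand_w) wins <- wins + 1L
  }
  expect_identical(wins, 20L)
})

test_that("simulated expression realises the within-pathway correlation", {
  d <- simulate_mutations(simulation_spec(n_genes = 40, n_samples = 2000,
                                          n_pathways = 2, set_size = 5),
                          seed = 12)
  E <- simulate_expression(d, within_corr = 0.8, seed = 13)
  expect_identical(dimnames(E), dimnames(d$mutations))
  within <- mean(vapply(d$truth, function(g) expression_concordance(E, g),
                        numeric(1)))
  expect_lt(abs(within - 0.8), 0.05)
  # across pathways and among passengers the correlation is near zero
  cross <- abs(cor(E[, d$truth[[1]][1]], E[, d$truth[[2]][1]]))
  expect_lt(cross, 0.1)
  # independence limit
  E0 <- simulate_expression(d, within_corr = 0, seed = 14)
  within0 <- mean(vapply(d$truth, function(g) expression_concordance(E0, g),
                         numeric(1)))
  expect_lt(within0, 0.06)
  # implanted sets are more coherent than random sets of the same size
  set.seed(15)
  rand_r <- mean(replicate(20, {
    expression_concordance(E, sample(colnames(E), 5))
  }))
  expect_gt(within, rand_r + 0.5)
  expect_error(simulate_expression(d, within_corr = 1), "within_corr")
  e1 <- simulate_expression(d, within_corr = 0.5, seed = 1)
  e2 <- simulate_expression(d, within_corr = 0.5, seed = 1)
  expect_identical(e1, e2)
})
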