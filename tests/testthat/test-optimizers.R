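test_that("acceptance probability follows the Boltzmann rule", {
  expect_equal(acceptance_probability(0, 5), 1)
  expect_equal(acceptance_probability(3, 5), 1)  # improvements capped at 1
  T0 <- 2.5
  expect_equal(acceptance_probability(-T0 * log(2), T0), 0.5)
  expect_equal(acceptance_probability(-T0, T0), exp(-1))
  expect_error(acceptance_probability(1, 0), "positive")
  expect_error(acceptance_probability(1, -2), "positive")
})

test_that("exhaustive enumeration agrees with an independent brute force", {
  A <- toy_matrix()
  fit <- exhaustive_optimize(A, 2)
  expect_identical(fit$best_set, c("g1", "g3"))
  expect_identical(fit$best_score$weight, 4L)
  # k = 1: most frequently mutated gene, lexicographic among ties (g1 vs g3)
  expect_identical(exhaustive_optimize(A, 1)$best_set, "g1")
  # k = n leaves no choice
  expect_identical(exhaustive_optimize(A, 4)$best_set, paste0("g", 1:4))

  set.seed(21)
  for (i in 1:25) {
    B <- random_mutation_matrix(sample(4:12, 1), sample(3:12, 1), p = 0.3)
    k <- sample.int(min(4L, ncol(B)), 1)
    ref <- brute_force_best(B, k)
    fit <- exhaustive_optimize(B, k)
    expect_identical(fit$best_score$weight, as.integer(ref$weight))
    expect_identical(sort(fit$best_set), ref$genes)  # identical tie-breaking too
  }
  expect_error(exhaustive_optimize(random_mutation_matrix(5, 30), 10,
                                   max_combinations = 1e4),
               "budget")
})

test_that("every optimizer solves the toy instance and validates inputs", {
  A <- toy_matrix()
  for (method in c("saga", "ga", "mcmc", "exhaustive")) {
    fit <- driver_pathways(A, 2, method = method, seed = 5)
    expect_identical(fit$best_score$weight, 4L)
    expect_identical(sort(coef(fit)), c("g1", "g3"))
    expect_identical(length(unique(coef(fit))), 2L)
  }
  expect_error(driver_pathways(A, 5, method = "saga"), "exceeds")
  expect_error(driver_pathways(A, 0, method = "ga"), "integer")
  expect_error(mcmc_optimize(A, 2, c = 1), "> 1")
  expect_error(mcmc_optimize(A, 2, c = 0.5), "> 1")
})

test_that("seeded runs are exactly reproducible and leave the RNG alone", {
  set.seed(1234)
  A <- random_mutation_matrix(30, 25, p = 0.15)
  before <- .Random.seed
  f1 <- saga_optimize(A, 3, seed = 99)
  expect_identical(.Random.seed, before)  # caller's stream untouched
  f2 <- saga_optimize(A, 3, seed = 99)
  expect_identical(f1$best_set, f2$best_set)
  expect_identical(f1$trajectory, f2$trajectory)
  g1 <- ga_optimize(A, 3, seed = 7)
  g2 <- ga_optimize(A, 3, seed = 7)
  expect_identical(g1$best_set, g2$best_set)
  m1 <- mcmc_optimize(A, 3, iterations = 2000, seed = 3)
  m2 <- mcmc_optimize(A, 3, iterations = 2000, seed = 3)
  expect_identical(m1$best_set, m2$best_set)
  expect_identical(m1$trajectory, m2$trajectory)
})

test_that("reported best score never decreases along any trajectory", {
  set.seed(8)
  A <- random_mutation_matrix(40, 20, p = 0.2)
  for (fit in list(saga_optimize(A, 3, seed = 2),
                   ga_optimize(A, 3, seed = 2),
                   mcmc_optimize(A, 3, iterations = 5000, seed = 2))) {
    expect_true(all(diff(fit$trajectory$best) >= 0))
    expect_equal(fit$best_value, max(fit$trajectory$best))
    expect_gte(fit$best_value, max(fit$trajectory$current) - 1e-9)
  }
})

test_that("a degenerate one-set search space is a fixed point", {
  # n == k: only one candidate set exists, so every method must return it
  A <- toy_matrix()[, 1:3]
  for (method in c("saga", "ga", "mcmc", "exhaustive")) {
    fit <- driver_pathways(A, 3, method = method, seed = 1)
    expect_identical(fit$best_set, c("g1", "g2", "g3"))
  }
  # all-identical columns: every 2-set ties; any valid pair is acceptable
  B <- matrix(rep(c(1L, 0L, 1L), 4), 3, 4,
              dimnames = list(paste0("s", 1:3), paste0("g", 1:4)))
  fit <- saga_optimize(B, 2, seed = 4)
  expect_identical(fit$best_score$weight, 2L * 2L - 4L)
  expect_true(all(diff(fit$trajectory$best) >= 0))
})

test_that("very large MCMC base behaves as a hill climb", {
  set.seed(77)
  A <- random_mutation_matrix(40, 15, p = 0.25)
  fit <- mcmc_optimize(A, 3, iterations = 4000, c = 1e6, seed = 10)
  # with c enormous, downhill acceptance ~ 0: current only improves or holds
  worse_frac <- fit$accepted_worse_moves / fit$evaluations
  expect_lt(worse_frac, 0.001)
})

test_that("stochastic optimizers recover the exact optimum on small instances", {
  set.seed(5150)
  hits <- c(saga = 0L, ga = 0L, mcmc = 0L)
  n_inst <- 20L
  for (i in seq_len(n_inst)) {
    A <- random_mutation_matrix(25, 12, p = 0.25)
    ref <- exhaustive_optimize(A, 3)$best_score$weight
    if (saga_optimize(A, 3, seed = i)$best_score$weight == ref)
      hits["saga"] <- hits["saga"] + 1L
    if (ga_optimize(A, 3, seed = i)$best_score$weight == ref)
      hits["ga"] <- hits["ga"] + 1L
    if (mcmc_optimize(A, 3, iterations = 10000, seed = i)$best_score$weight == ref)
      hits["mcmc"] <- hits["mcmc"] + 1L
  }
  expect_true(all(hits == n_inst))
})

test_that("the integrative objective at lambda = 0 mirrors the weight objective", {
  set.seed(31)
  A <- random_mutation_matrix(30, 15, p = 0.25)
  E <- matrix(rnorm(30 * 15), 30, 15, dimnames = dimnames(A))
  fw <- saga_optimize(A, 3, seed = 12)
  fi <- saga_optimize(A, 3, objective = "integrative", expression = E,
                      lambda = 0, seed = 12)
  expect_identical(fw$best_set, fi$best_set)
  expect_equal(fi$best_score$score, as.numeric(fw$best_score$weight))
})

test_that("the integrative objective breaks ties toward co-expressed sets", {
  # two candidate pairs with identical mutation weight; only one is
  # co-expressed, so F_ME must prefer it for lambda > 0
  A <- matrix(0L, 6, 4, dimnames = list(paste0("s", 1:6), c("a1", "a2", "b1", "b2")))
  A[1:3, "a1"] <- 1L; A[4:6, "a2"] <- 1L
  A[1:3, "b1"] <- 1L; A[4:6, "b2"] <- 1L
  set.seed(2)
  f <- rnorm(6)
  E <- cbind(a1 = f + 0.01 * rnorm(6), a2 = f + 0.01 * rnorm(6),
             b1 = rnorm(6), b2 = rnorm(6))
  rownames(E) <- rownames(A)
  fit <- exhaustive_optimize(A, 2, objective = "integrative",
                             expression = E, lambda = 1)
  expect_identical(fit$best_set, c("a1", "a2"))
  expect_identical(fit$best_score$weight, 6L)
})
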