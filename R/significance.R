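#' Permute a mutation matrix preserving per-gene mutation counts
#'
#' The permutation null model reassigns each gene's mutations to a uniformly
#' random subset of samples of the same size, independently per gene.  Per-
#' gene mutation frequencies are preserved exactly; any coverage/exclusivity
#' structure among genes is destroyed.
#'
#' @param A binary mutation matrix.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return a permuted mutation matrix with the same dimnames and column sums.
#' @export
permute_mutations <- function(A, seed = NULL) {
  A <- validate_mutation_matrix(A)
  m <- nrow(A)
  with_seed(seed, {
    out <- matrix(0L, m, ncol(A), dimnames = dimnames(A))
    counts <- colSums(A)
    for (j in seq_len(ncol(A))) {
      if (counts[j] > 0L) out[sample.int(m, counts[j]), j] <- 1L
    }
    out
  })
}

#' Permutation test for the weight of a discovered gene set
#'
#' Assesses whether an observed maximum weight could arise from genes with
#' the same mutation frequencies but no coverage/exclusivity structure.  Each
#' of `n_perm` permuted matrices ([permute_mutations()]) is re-optimised at
#' the same k with the configured optimizer, and the add-one estimator
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)` is reported, so p can
#' never be exactly zero and its floor is `1 / (n_perm + 1)`.
#'
#' @param A binary mutation matrix.
#' @param k gene-set size that produced the observed weight.
#' @param observed_weight the weight being tested (e.g.
#'   `fit$best_score$weight`).
#' @param n_perm number of permutations.
#' @param method optimizer used on each permuted matrix (`"exhaustive"` when
#'   feasible; any [driver_pathways()] method otherwise).
#' @param seed integer seed; permutation i uses a seed derived from it.
#' @param ... passed to the optimizer.
#' @return a list of class `permutation_test` with `observed_weight`,
#'   `null_weights`, `p_value`, `n_perm`, `seed`.
#' @export
permutation_test <- function(A, k, observed_weight, n_perm = 1000L,
                             method = "exhaustive", seed = NULL, ...) {
  A <- validate_mutation_matrix(A)
  n_perm <- check_count(n_perm, "n_perm")
  stopifnot(is.numeric(observed_weight), length(observed_weight) == 1L)
  null_weights <- vapply(seq_len(n_perm), function(i) {
    Ap <- permute_mutations(A, seed = derive_seed(seed, i))
    fit <- driver_pathways(Ap, k, method = method,
                           seed = derive_seed(seed, n_perm + i), ...)
    fit$best_score$weight
  }, numeric(1))
  p <- (1 + sum(null_weights >= observed_weight)) / (1 + n_perm)
  structure(list(observed_weight = observed_weight,
                 null_weights = null_weights,
                 p_value = p, n_perm = n_perm, seed = seed,
                 method = method),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("Permutation test (%d permutations, %s optimizer)\n",
              x$n_perm, x$method))
  cat(sprintf("  observed weight %g vs null max %g (median %g); p = %.4g\n",
              x$observed_weight, max(x$null_weights),
              stats::median(x$null_weights), x$p_value))
  invisible(x)
}

#' Iterative remove-and-rediscover pathway discovery
#'
#' Discovers several pathways in turn: at each stage the optimizer finds the
#' best set of the scheduled size, a permutation test scores it, and the
#' found genes' columns are removed before the next stage, so later stages
#' see only the remaining signal ("second optimal patterns").
#'
#' @param A binary mutation matrix.
#' @param schedule integer vector of k values, one per stage.
#' @param method optimizer for both discovery and the permutation null.
#' @param n_perm permutations per stage.
#' @param seed integer seed; each stage derives its own stream.
#' @param ... passed to the optimizer.
#' @return a list of class `discovery_path`; each stage holds `fit`
#'   (a `driver_fit`), `test` (a `permutation_test`) and `k`.  If the matrix
#'   runs out of genes mid-schedule an error of class `sagapath_exhausted`
#'   is thrown carrying the completed stages in its `stages` field.
#' @export
iterative_discovery <- function(A, schedule, method = "exhaustive",
                                n_perm = 100L, seed = NULL, ...) {
  A <- validate_mutation_matrix(A)
  if (length(schedule) < 1L) stop_f("`schedule` must list at least one stage")
  schedule <- vapply(seq_along(schedule),
                     function(i) check_count(schedule[i], "schedule"), integer(1))
  stages <- vector("list", length(schedule))
  current <- A
  for (s in seq_along(schedule)) {
    k <- schedule[s]
    if (ncol(current) < k) {
      cond <- structure(
        class = c("sagapath_exhausted", "error", "condition"),
        list(message = sprintf(
          "gene matrix exhausted after %d completed stage(s): stage %d needs k = %d but only %d genes remain",
          s - 1L, s, k, ncol(current)),
          call = sys.call(-1), stages = stages[seq_len(s - 1L)])
      )
      stop(cond)
    }
    fit <- driver_pathways(current, k, method = method,
                           seed = derive_seed(seed, 2L * s), ...)
    test <- permutation_test(current, k, fit$best_score$weight,
                             n_perm = n_perm, method = method,
                             seed = derive_seed(seed, 2L * s + 1L), ...)
    stages[[s]] <- list(k = k, fit = fit, test = test,
                        genes = fit$best_set)
    current <- current[, setdiff(colnames(current), fit$best_set), drop = FALSE]
  }
  structure(list(stages = stages, schedule = schedule, seed = seed,
                 remaining_genes = colnames(current)),
            class = "discovery_path")
}

#' @export
print.discovery_path <- function(x, ...) {
  cat(sprintf("Iterative discovery: %d stage(s)\n", length(x$stages)))
  for (s in seq_along(x$stages)) {
    st <- x$stages[[s]]
    cat(sprintf("  stage %d (k = %d): %s  W = %d  p = %.4g\n", s, st$k,
                paste(st$genes, collapse = ", "),
                st$fit$best_score$weight, st$test$p_value))
  }
  invisible(x)
}

#' Optimizer accuracy benchmark against the exact oracle
#'
#' Repeats the implanted-pathway simulation and asks, per replicate, whether
#' each stochastic optimizer attains the exact optimal weight at
#' `k = spec$set_size`.  The exact optimum is computed by exhaustive
#' enumeration over a candidate pool consisting of every implanted gene plus
#' the `pool_extra` most frequently mutated passenger genes (full enumeration
#' over all `choose(n, k)` sets being out of reach); a match means equal
#' weight, not identical gene ids, since distinct optima of equal weight are
#' legitimate.  The MCMC baseline is run with its evaluation budget matched
#' to the number of evaluations SAGA spent on the same replicate.
#'
#' @param spec a [simulation_spec()].
#' @param methods subset of `c("saga", "ga", "mcmc")`.
#' @param n_replicates simulated instances.
#' @param seed integer seed; replicate r derives simulation and optimizer
#'   streams from it.
#' @param pool_extra top-frequency passenger genes added to the oracle pool.
#' @param mcmc_iterations fixed MCMC budget; `NULL` (default) matches SAGA's
#'   per-replicate evaluation count (or 20000 if SAGA is not run).
#' @param anneal,ga optimizer controls, as in [saga_optimize()].
#' @return a list of class `benchmark_result`: `accuracy` (named fraction of
#'   replicates matching the oracle per method) and `records` (one row per
#'   replicate x method with the returned and oracle weights).
#' @export
accuracy_benchmark <- function(spec, methods = c("saga", "ga", "mcmc"),
                               n_replicates = 100L, seed = NULL,
                               pool_extra = 15L, mcmc_iterations = NULL,
                               anneal = anneal_control(), ga = ga_control()) {
  stopifnot(inherits(spec, "simulation_spec"))
  methods <- match.arg(methods, c("saga", "ga", "mcmc"), several.ok = TRUE)
  n_replicates <- check_count(n_replicates, "n_replicates")
  pool_extra <- check_count(pool_extra, "pool_extra", min = 0L)
  k <- spec$set_size
  records <- vector("list", n_replicates * length(methods))
  rec_i <- 0L
  for (r in seq_len(n_replicates)) {
    d <- simulate_mutations(spec, seed = derive_seed(seed, 17L * r))
    A <- d$mutations
    truth_genes <- unlist(d$truth, use.names = FALSE)
    extra <- setdiff(names(sort(colSums(A), decreasing = TRUE)), truth_genes)
    pool <- c(truth_genes, extra[seq_len(min(pool_extra, length(extra)))])
    oracle <- exhaustive_optimize(A[, pool, drop = FALSE], k)
    saga_evals <- NULL
    for (method in methods) {
      mseed <- derive_seed(seed, 17L * r + match(method, c("saga", "ga", "mcmc")))
      fit <- switch(method,
        saga = saga_optimize(A, k, anneal = anneal, ga = ga, seed = mseed),
        ga = ga_optimize(A, k, control = ga, seed = mseed),
        mcmc = mcmc_optimize(
          A, k,
          iterations = mcmc_iterations %||% saga_evals %||% 20000L,
          seed = mseed
        )
      )
      if (method == "saga") saga_evals <- fit$evaluations
      rec_i <- rec_i + 1L
      records[[rec_i]] <- data.frame(
        replicate = r, method = method,
        returned_set = paste(fit$best_set, collapse = "+"),
        returned_weight = fit$best_score$weight,
        oracle_weight = oracle$best_score$weight,
        match = fit$best_score$weight == oracle$best_score$weight,
        stringsAsFactors = FALSE
      )
    }
  }
  records <- do.call(rbind, records)
  accuracy <- vapply(methods, function(mm) {
    mean(records$match[records$method == mm])
  }, numeric(1))
  structure(list(accuracy = accuracy, records = records,
                 n_replicates = n_replicates, spec = spec, seed = seed),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("Optimizer accuracy vs exact oracle (%d replicates)\n",
              x$n_replicates))
  for (mm in names(x$accuracy)) {
    cat(sprintf("  %-5s %5.1f%%\n", mm, 100 * x$accuracy[[mm]]))
  }
  invisible(x)
}
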