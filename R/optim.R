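#' Simulated-annealing acceptance probability
#'
#' Probability of accepting a move with score change `delta` at temperature
#' `T`: `min(1, exp(delta / T))`.  Improvements (`delta >= 0`) are always
#' accepted; worse moves are accepted with the Boltzmann probability, which
#' shrinks as the temperature falls.
#'
#' @param delta numeric vector of score changes (proposal minus current).
#' @param temperature single positive temperature.
#' @return numeric vector of probabilities in (0, 1].
#' @export
acceptance_probability <- function(delta, temperature) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop_f("`temperature` must be a single positive number")
  }
  pmin(1, exp(delta / temperature))
}

metropolis_accept <- function(delta, temperature) {
  delta >= 0 || stats::runif(1) < acceptance_probability(delta, temperature)
}

# Evaluator bundle over column indices:
#   one(idx)    objective of one set
#   many(sets)  objective of each column of a k x P index matrix
#   refine(idx) greedy 1-swap local optimum of the weight part (Lamarckian
#               refinement; for the integrative objective the refined set is
#               re-scored with the full objective)
# F_ME with lambda = 0 is identically W, so it takes the weight path and the
# two objectives draw the same random numbers.
make_evaluator <- function(A, objective, expression = NULL, lambda = 1) {
  if (objective == "integrative" && lambda == 0) objective <- "weight"
  packed <- pack_mutations_cpp(A)
  w_one <- function(idx) packed_weights_cpp(packed, matrix(as.integer(idx)))[1]
  w_many <- function(sets) packed_weights_cpp(packed, sets)
  top_genes <- function(t) order(packed$counts, decreasing = TRUE)[seq_len(t)]
  grow <- function(gene, k) greedy_grow_cpp(packed, gene, k)
  if (objective == "weight") {
    return(list(
      one = w_one, many = w_many, top_genes = top_genes, grow = grow,
      refine = function(idx) {
        r <- local_search_cpp(packed, as.integer(idx))
        list(set = r$set, value = r$weight, evals = r$evaluated)
      }
    ))
  }
  if (is.null(expression)) {
    stop_f("the integrative objective needs an expression matrix")
  }
  if (!identical(colnames(expression), colnames(A)) ||
      !identical(rownames(expression), rownames(A))) {
    stop_f("mutation and expression matrices are not aligned; see align_matrices()")
  }
  rterm <- function(idx) {
    cm <- suppressWarnings(stats::cor(expression[, idx, drop = FALSE],
                                      use = "pairwise.complete.obs"))
    vals <- abs(cm[upper.tri(cm)])
    vals[is.na(vals)] <- 0
    mean(vals)
  }
  one <- function(idx) w_one(idx) + lambda * rterm(idx)
  list(
    one = one,
    top_genes = top_genes, grow = grow,
    many = function(sets) {
      w_many(sets) + lambda * apply(sets, 2L, rterm)
    },
    refine = function(idx) {
      r <- local_search_cpp(packed, as.integer(idx))
      list(set = r$set, value = one(r$set), evals = r$evaluated)
    }
  )
}

random_set <- function(n, k) sort(sample.int(n, k))

random_population <- function(n, k, P) {
  matrix(vapply(seq_len(P), function(i) random_set(n, k), integer(k)), nrow = k)
}

# Initial population: random individuals plus greedy forward-selected sets
# grown from the most frequently mutated genes, one seed per top gene.  The
# seeds place whole-pathway building blocks in the gene pool from the start;
# the returned eval count covers the greedy growth.
seeded_population <- function(ev, n, k, P, n_seeds) {
  pop <- random_population(n, k, P)
  n_seeds <- min(n_seeds, P - 1L, n)
  evals <- 0
  if (n_seeds > 0L && k > 1L) {
    tops <- ev$top_genes(n_seeds)
    for (i in seq_len(n_seeds)) {
      g <- ev$grow(tops[i], k)
      pop[, i] <- g$set
      evals <- evals + g$evaluated
    }
  }
  list(pop = pop, evals = evals)
}

mutate_set <- function(set, n) {
  if (length(set) >= n) return(set)  # no non-member exists
  pos <- if (length(set) == 1L) 1L else sample.int(length(set), 1L)
  repeat {
    g <- sample.int(n, 1L)
    if (!(g %in% set)) break
  }
  set[pos] <- g
  sort(set)
}

crossover_sets <- function(p1, p2, n) {
  k <- length(p1)
  if (k == 1L) return(p1)
  cut <- sample.int(k - 1L, 1L)
  child <- unique(c(p1[seq_len(cut)], p2[(cut + 1L):k]))
  while (length(child) < k) {
    g <- sample.int(n, 1L)
    if (!(g %in% child)) child <- c(child, g)
  }
  sort(child)
}

# One GA generation on a k x P population matrix: tournament selection
# (size 2), one-point crossover with duplicate repair, single-member
# mutation, elitism.  `inject` replaces the worst individual beforehand,
# anchoring the generation in the annealer's current solution.
ga_generation <- function(pop, fit, ev, n, ctrl, inject = NULL,
                          inject_value = NULL) {
  P <- ncol(pop)
  k <- nrow(pop)
  evals <- 0
  if (!is.null(inject)) {
    worst <- which.min(fit)
    pop[, worst] <- inject
    if (is.null(inject_value)) {
      inject_value <- ev$one(inject)
      evals <- evals + 1
    }
    fit[worst] <- inject_value
  }
  elite_n <- ctrl$elite_count
  children <- pop
  child_fit <- fit
  if (elite_n > 0L) {
    elite_idx <- order(fit, decreasing = TRUE)[seq_len(elite_n)]
    children[, seq_len(elite_n)] <- pop[, elite_idx]
    child_fit[seq_len(elite_n)] <- fit[elite_idx]
  }
  n_child <- P - elite_n
  # one batch of random draws per generation (tournament size 2; first
  # candidate wins fitness ties, matching which.max)
  cand <- matrix(sample.int(P, 4L * n_child, replace = TRUE), nrow = 4L)
  par1 <- ifelse(fit[cand[1L, ]] >= fit[cand[2L, ]], cand[1L, ], cand[2L, ])
  par2 <- ifelse(fit[cand[3L, ]] >= fit[cand[4L, ]], cand[3L, ], cand[4L, ])
  do_cross <- stats::runif(n_child) < ctrl$crossover_probability
  cuts <- if (k > 1L) sample.int(k - 1L, n_child, replace = TRUE) else
    integer(n_child)
  do_mut <- stats::runif(n_child) < ctrl$mutation_probability
  mut_pos <- sample.int(k, n_child, replace = TRUE)
  for (i in seq_len(n_child)) {
    child <- pop[, par1[i]]
    if (do_cross[i] && k > 1L) {
      child <- unique.default(c(child[seq_len(cuts[i])],
                                pop[(cuts[i] + 1L):k, par2[i]]))
      while (length(child) < k) {  # duplicate repair with unused genes
        g <- sample.int(n, 1L)
        if (!(g %in% child)) child <- c(child, g)
      }
    }
    if (do_mut[i] && k < n) {
      repeat {
        g <- sample.int(n, 1L)
        if (!(g %in% child)) break
      }
      child[mut_pos[i]] <- g
    }
    children[, elite_n + i] <- sort.int(child)
  }
  fresh <- elite_n + seq_len(n_child)
  if (n_child > 0L) {
    child_fit[fresh] <- ev$many(children[, fresh, drop = FALSE])
    evals <- evals + n_child
  }
  list(pop = children, fit = child_fit, evals = evals)
}

new_driver_fit <- function(A, method, k, best_idx, best_value, trajectory,
                           accepted_worse, evaluations, seed, objective,
                           expression = NULL, lambda = 1) {
  genes <- colnames(A)[sort(best_idx)]
  best_score <- if (objective == "integrative") {
    integrative_score(A, expression, genes, lambda, zero_variance = "zero")
  } else {
    pathway_weight(A, genes)
  }
  structure(list(
    best_set = genes,
    best_score = best_score,
    best_value = best_value,
    trajectory = trajectory,
    accepted_worse_moves = accepted_worse,
    evaluations = evaluations,
    rng_seed = seed,
    method = method,
    objective = objective,
    lambda = if (objective == "integrative") lambda,
    k = k,
    n_genes = ncol(A),
    n_samples = nrow(A)
  ), class = "driver_fit")
}

check_k <- function(A, k) {
  k <- check_count(k, "k")
  if (k > ncol(A)) {
    stop_f("k = %d exceeds the number of genes (%d)", k, ncol(A))
  }
  k
}

#' Simulated annealing hybrid genetic algorithm (SAGA)
#'
#' Searches for the size-k gene set maximising the coverage/exclusivity
#' weight (or the integrative score).  A genetic algorithm supplies the
#' initial solution and, throughout the run, generates each new proposal in
#' the neighbourhood of the current solution: one GA generation of a
#' persistent population with the current solution injected, taking the best
#' offspring that differs from it (`neighborhood = "swap"` uses a cheap
#' single-gene swap instead).  Proposals are refined to their greedy 1-swap
#' local optimum before the Metropolis decision: improving proposals are
#' always taken, worse ones accepted with probability `exp(delta / T)` under
#' a geometric cooling schedule.  Because distinct near-optimal gene sets sit
#' in deep, widely separated basins of the weight landscape, a temperature
#' stage that fails to improve the best solution re-initialises the
#' population at random (the algorithm's outer loop re-enters its
#' GA-initialisation step), so the run behaves as a record-keeping
#' multi-start anneal.
#'
#' @param A binary mutation matrix (samples x genes).
#' @param k gene-set size to search for.
#' @param anneal an [anneal_control()] list.
#' @param ga a [ga_control()] list (proposal-generation parameters).
#' @param objective `"weight"` for W(M) or `"integrative"` for F_ME.
#' @param expression expression matrix aligned with `A` (integrative only).
#' @param lambda expression-term coefficient (integrative only).
#' @param seed integer seed making the run reproducible; `NULL` uses the
#'   current RNG stream.
#' @param neighborhood `"ga"` (default) or `"swap"` proposal generator.
#' @param init_generations GA generations used to build the initial solution.
#' @param refine apply greedy local-search refinement to proposals (default
#'   `TRUE`; refinement optimises the weight part of the objective).
#' @return an object of class `driver_fit`; see [driver_pathways()].
#' @export
saga_optimize <- function(A, k, anneal = anneal_control(), ga = ga_control(),
                          objective = c("weight", "integrative"),
                          expression = NULL, lambda = 1, seed = NULL,
                          neighborhood = c("ga", "swap"),
                          init_generations = 10L, refine = TRUE) {
  A <- validate_mutation_matrix(A)
  k <- check_k(A, k)
  objective <- match.arg(objective)
  neighborhood <- match.arg(neighborhood)
  stopifnot(inherits(anneal, "anneal_control"), inherits(ga, "ga_control"))
  init_generations <- check_count(init_generations, "init_generations", min = 0L)
  n <- ncol(A)
  t0 <- anneal$initial_temperature %||% max(nrow(A) / 10, 10 * anneal$min_temperature)

  with_seed(seed, {
    ev <- make_evaluator(A, objective, expression, lambda)
    P <- ga$population_size
    sp <- seeded_population(ev, n, k, P, ga$greedy_seeds)
    pop <- sp$pop
    fit <- ev$many(pop)
    evals <- P + sp$evals
    for (g in seq_len(init_generations)) {
      step <- ga_generation(pop, fit, ev, n, ga)
      pop <- step$pop; fit <- step$fit; evals <- evals + step$evals
    }
    cur_idx <- pop[, which.max(fit)]
    cur_val <- max(fit)
    if (refine) {
      r <- ev$refine(cur_idx)
      cur_idx <- r$set; cur_val <- r$value; evals <- evals + r$evals
    }
    best_idx <- cur_idx
    best_val <- cur_val

    max_stages <- max(1L, ceiling(log(anneal$min_temperature / t0) /
                                    log(anneal$cooling_factor)) + 1L)
    cap <- max_stages * anneal$steps_per_temperature
    tr_t <- numeric(cap); tr_cur <- numeric(cap); tr_best <- numeric(cap)
    it <- 0L
    temp <- t0
    stagnant <- 0L
    accepted_worse <- 0L

    while (temp >= anneal$min_temperature && stagnant < anneal$max_stagnant_rounds) {
      improved <- FALSE
      for (s in seq_len(anneal$steps_per_temperature)) {
        if (neighborhood == "ga") {
          for (g in seq_len(ga$generations_per_proposal)) {
            step <- ga_generation(pop, fit, ev, n, ga,
                                  inject = cur_idx, inject_value = cur_val)
            pop <- step$pop; fit <- step$fit; evals <- evals + step$evals
          }
          differs <- colSums(pop != cur_idx) > 0L
          if (any(differs)) {
            j <- which(differs)[which.max(fit[differs])]
            prop_idx <- pop[, j]
            prop_val <- fit[j]
          } else {
            prop_idx <- mutate_set(cur_idx, n)
            prop_val <- ev$one(prop_idx)
            evals <- evals + 1
          }
        } else {
          prop_idx <- mutate_set(cur_idx, n)
          prop_val <- ev$one(prop_idx)
          evals <- evals + 1
        }
        if (refine) {
          r <- ev$refine(prop_idx)
          prop_idx <- r$set; prop_val <- r$value; evals <- evals + r$evals
        }
        delta <- prop_val - cur_val
        if (delta > 0 || metropolis_accept(delta, temp)) {
          if (delta < 0) accepted_worse <- accepted_worse + 1L
          cur_idx <- prop_idx
          cur_val <- prop_val
          if (cur_val > best_val) {
            best_val <- cur_val
            best_idx <- cur_idx
            improved <- TRUE
          }
        }
        it <- it + 1L
        tr_t[it] <- temp; tr_cur[it] <- cur_val; tr_best[it] <- best_val
      }
      temp <- temp * anneal$cooling_factor
      if (improved) {
        stagnant <- 0L
      } else {
        stagnant <- stagnant + 1L
        # re-enter the GA initialisation step: fresh population, so the next
        # stage proposes from a new region while best/current are retained
        pop <- random_population(n, k, P)
        fit <- ev$many(pop)
        evals <- evals + P
      }
    }

    trajectory <- data.frame(iteration = seq_len(it),
                             temperature = tr_t[seq_len(it)],
                             current = tr_cur[seq_len(it)],
                             best = tr_best[seq_len(it)])
    new_driver_fit(A, "saga", k, best_idx, best_val, trajectory,
                   accepted_worse, evals, seed, objective, expression, lambda)
  })
}

#' Genetic-algorithm baseline optimizer
#'
#' Generational GA over sorted k-tuples of gene indices: tournament selection
#' (size 2), one-point crossover with duplicate repair, single-member
#' mutation, elitism, plus greedy local-search refinement of each
#' generation's best offspring (memetic step; without it the GA cannot cross
#' the deep valleys separating near-optimal gene sets).
#'
#' @inheritParams saga_optimize
#' @param control a [ga_control()] list; `control$generations` generations
#'   are run.
#' @param refine apply local-search refinement to each generation's best
#'   offspring.
#' @return an object of class `driver_fit`.
#' @export
ga_optimize <- function(A, k, control = ga_control(),
                        objective = c("weight", "integrative"),
                        expression = NULL, lambda = 1, seed = NULL,
                        refine = TRUE) {
  A <- validate_mutation_matrix(A)
  k <- check_k(A, k)
  objective <- match.arg(objective)
  stopifnot(inherits(control, "ga_control"))
  n <- ncol(A)

  with_seed(seed, {
    ev <- make_evaluator(A, objective, expression, lambda)
    P <- control$population_size
    sp <- seeded_population(ev, n, k, P, control$greedy_seeds)
    pop <- sp$pop
    fit <- ev$many(pop)
    evals <- P + sp$evals
    best_i <- which.max(fit)
    best_idx <- pop[, best_i]
    best_val <- fit[best_i]
    G <- control$generations
    tr_cur <- numeric(G); tr_best <- numeric(G)
    for (g in seq_len(G)) {
      step <- ga_generation(pop, fit, ev, n, control)
      pop <- step$pop; fit <- step$fit; evals <- evals + step$evals
      if (refine) {
        j <- which.max(fit)
        r <- ev$refine(pop[, j])
        evals <- evals + r$evals
        if (r$value > fit[j]) {
          pop[, j] <- r$set
          fit[j] <- r$value
        }
      }
      gen_best <- which.max(fit)
      if (fit[gen_best] > best_val) {
        best_val <- fit[gen_best]
        best_idx <- pop[, gen_best]
      }
      tr_cur[g] <- fit[gen_best]; tr_best[g] <- best_val
    }
    trajectory <- data.frame(iteration = seq_len(G), temperature = NA_real_,
                             current = tr_cur, best = tr_best)
    new_driver_fit(A, "ga", k, best_idx, best_val, trajectory,
                   0L, evals, seed, objective, expression, lambda)
  })
}

#' Markov chain Monte Carlo baseline optimizer
#'
#' Single-gene-swap Metropolis chain whose stationary distribution is
#' proportional to `c^W(M)`: a proposed swap with weight change `delta` is
#' accepted with probability `min(1, c^delta)`.  Larger `c` concentrates the
#' chain on high-weight sets; the best state visited is reported.
#'
#' @inheritParams saga_optimize
#' @param iterations number of proposed swaps.
#' @param c Metropolis base, > 1.
#' @param thin record the trajectory every `thin` iterations; `NULL` keeps
#'   the record near 10,000 rows.
#' @return an object of class `driver_fit`.
#' @export
mcmc_optimize <- function(A, k, iterations = 20000L, c = 2, seed = NULL,
                          objective = c("weight", "integrative"),
                          expression = NULL, lambda = 1, thin = NULL) {
  A <- validate_mutation_matrix(A)
  k <- check_k(A, k)
  objective <- match.arg(objective)
  iterations <- check_count(iterations, "iterations")
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 1) {
    stop_f("`c` must be a single number > 1")
  }
  thin <- if (is.null(thin)) max(1L, iterations %/% 10000L) else
    check_count(thin, "thin")
  n <- ncol(A)
  if (k == n) {  # single candidate set; no swap proposal exists
    trajectory <- data.frame(iteration = 1L, temperature = NA_real_,
                             current = NA_real_, best = NA_real_)
    fit <- new_driver_fit(A, "mcmc", k, seq_len(n), NA_real_, trajectory,
                          0L, 1, seed, objective, expression, lambda)
    fit$best_value <- fit$best_score$score
    fit$trajectory$current <- fit$best_value
    fit$trajectory$best <- fit$best_value
    return(fit)
  }

  with_seed(seed, {
    if (objective == "weight" || lambda == 0) {
      packed <- pack_mutations_cpp(A)
      res <- mcmc_chain_cpp(packed, random_set(n, k), iterations, c, thin)
      trajectory <- data.frame(iteration = res$iteration,
                               temperature = NA_real_,
                               current = res$current, best = res$best)
      return(new_driver_fit(A, "mcmc", k, res$set, res$weight, trajectory,
                            as.integer(res$accepted_worse), res$evaluated,
                            seed, objective, expression, lambda))
    }
    ev <- make_evaluator(A, objective, expression, lambda)
    cur_idx <- random_set(n, k)
    cur_val <- ev$one(cur_idx)
    evals <- 1
    best_idx <- cur_idx
    best_val <- cur_val
    accepted_worse <- 0L
    keep <- seq_len(iterations %/% thin) * thin
    tr_cur <- numeric(length(keep)); tr_best <- numeric(length(keep))
    rec <- 0L
    log_c <- log(c)
    for (i in seq_len(iterations)) {
      prop_idx <- mutate_set(cur_idx, n)
      prop_val <- ev$one(prop_idx)
      evals <- evals + 1
      delta <- prop_val - cur_val
      if (delta >= 0 || stats::runif(1) < exp(log_c * delta)) {
        if (delta < 0) accepted_worse <- accepted_worse + 1L
        cur_idx <- prop_idx
        cur_val <- prop_val
        if (cur_val > best_val) {
          best_val <- cur_val
          best_idx <- cur_idx
        }
      }
      if (i %% thin == 0L) {
        rec <- rec + 1L
        tr_cur[rec] <- cur_val; tr_best[rec] <- best_val
      }
    }
    trajectory <- data.frame(iteration = keep,
                             temperature = NA_real_,
                             current = tr_cur, best = tr_best)
    new_driver_fit(A, "mcmc", k, best_idx, best_val, trajectory,
                   accepted_worse, evals, seed, objective, expression, lambda)
  })
}

#' Exact maximum-weight gene set by exhaustive enumeration
#'
#' Enumerates all `choose(n, k)` gene sets and returns the true optimum.
#' Ties are broken lexicographically on the sorted gene ids, so the result is
#' fully deterministic.  The weight objective runs in compiled code over
#' bit-packed columns; problems with more than `max_combinations` candidate
#' sets are refused (restrict the matrix to a candidate gene pool, as
#' [accuracy_benchmark()] does, or use a stochastic optimizer).
#'
#' @inheritParams saga_optimize
#' @param max_combinations enumeration budget guard.
#' @return an object of class `driver_fit`.
#' @export
exhaustive_optimize <- function(A, k, objective = c("weight", "integrative"),
                                expression = NULL, lambda = 1,
                                max_combinations = 2e6) {
  A <- validate_mutation_matrix(A)
  k <- check_k(A, k)
  objective <- match.arg(objective)
  n <- ncol(A)
  n_comb <- choose(n, k)
  if (n_comb > max_combinations) {
    stop_f(paste0("choose(%d, %d) = %.3g sets exceeds the enumeration budget (%.3g); ",
                  "restrict the gene pool or use a stochastic optimizer"),
           n, k, n_comb, max_combinations)
  }
  ord <- order(colnames(A))  # id-lexicographic tie-break via enumeration order
  B <- A[, ord, drop = FALSE]
  if (objective == "weight" || lambda == 0) {
    res <- exact_max_weight_cpp(B, k)
    best_idx <- ord[res$indices]
    best_val <- res$weight
    if (objective == "integrative") {
      best_val <- make_evaluator(A, objective, expression, lambda)$one(best_idx)
    }
  } else {
    ev <- make_evaluator(A, objective, expression, lambda)
    combos <- utils::combn(n, k)
    vals <- ev$many(matrix(ord[combos], nrow = k))
    best_j <- which.max(vals)
    best_val <- vals[best_j]
    best_idx <- ord[combos[, best_j]]
  }
  trajectory <- data.frame(iteration = 1L, temperature = NA_real_,
                           current = best_val, best = best_val)
  new_driver_fit(A, "exhaustive", k, best_idx, best_val, trajectory,
                 0L, as.integer(min(n_comb, .Machine$integer.max)), NULL,
                 objective, expression, lambda)
}

#' Find a maximum-weight driver gene set
#'
#' Front door for the maximum weight submatrix problem: choose k gene columns
#' of a binary mutation matrix maximising
#' `W(M) = 2|Gamma(M)| - sum_g |Gamma(g)|`, i.e. covering many samples with
#' near-mutually-exclusive mutations.  With an expression matrix the
#' integrative objective `F_ME = W(M) + lambda R(E_M)` is maximised instead.
#'
#' @param mutations binary mutation matrix (samples x genes), e.g. from
#'   [read_mutation_matrix()] or [simulate_mutations()].
#' @param k gene-set size.
#' @param method `"saga"` (default), `"ga"`, `"mcmc"` or `"exhaustive"`.
#' @param expression optional aligned expression matrix; switches the
#'   objective to F_ME.
#' @param lambda expression-term coefficient (reference settings: 1 and 10).
#' @param seed integer seed; identical seeds give identical fits.
#' @param ... passed to the selected optimizer ([saga_optimize()],
#'   [ga_optimize()], [mcmc_optimize()], [exhaustive_optimize()]).
#' @return an object of class `driver_fit` with components `best_set`
#'   (gene ids), `best_score` (a [pathway_weight()]-style score object),
#'   `trajectory` (per-iteration current/best score and temperature),
#'   `accepted_worse_moves`, `evaluations` and `rng_seed`.  Methods:
#'   `print`, `summary`, `coef` (the gene ids), `plot` (search trajectory).
#' @examples
#' A <- matrix(0L, 4, 4, dimnames = list(paste0("s", 1:4), paste0("g", 1:4)))
#' A["s1", "g1"] <- A["s2", "g1"] <- A["s3", "g2"] <- A["s3", "g3"] <- A["s4", "g3"] <- 1L
#' fit <- driver_pathways(A, k = 2, method = "exhaustive")
#' coef(fit)
#' @export
driver_pathways <- function(mutations, k,
                            method = c("saga", "ga", "mcmc", "exhaustive"),
                            expression = NULL, lambda = 1, seed = NULL, ...) {
  method <- match.arg(method)
  objective <- if (is.null(expression)) "weight" else "integrative"
  fit <- switch(method,
    saga = saga_optimize(mutations, k, objective = objective,
                         expression = expression, lambda = lambda,
                         seed = seed, ...),
    ga = ga_optimize(mutations, k, objective = objective,
                     expression = expression, lambda = lambda,
                     seed = seed, ...),
    mcmc = mcmc_optimize(mutations, k, objective = objective,
                         expression = expression, lambda = lambda,
                         seed = seed, ...),
    exhaustive = exhaustive_optimize(mutations, k, objective = objective,
                                     expression = expression, lambda = lambda,
                                     ...)
  )
  fit$call <- match.call()
  fit
}

#' @export
print.driver_fit <- function(x, ...) {
  cat(sprintf("Driver pathway fit (%s, k = %d, %d genes x %d samples)\n",
              x$method, x$k, x$n_genes, x$n_samples))
  print(x$best_score)
  invisible(x)
}

#' @export
summary.driver_fit <- function(object, ...) {
  x <- object
  print(x)
  cat(sprintf("  objective: %s%s\n", x$objective,
              if (x$objective == "integrative") sprintf(" (lambda = %g)", x$lambda) else ""))
  cat(sprintf("  evaluations: %.0f; worse moves accepted: %d\n",
              x$evaluations, x$accepted_worse_moves))
  if (!is.null(x$rng_seed)) cat(sprintf("  seed: %d\n", x$rng_seed))
  invisible(x)
}

#' @export
coef.driver_fit <- function(object, ...) object$best_set

#' @export
plot.driver_fit <- function(x, ...) {
  tr <- x$trajectory
  plot(tr$iteration, tr$best, type = "l", lwd = 2,
       xlab = "iteration", ylab = "score",
       main = sprintf("%s search trajectory", x$method), ...)
  lines(tr$iteration, tr$current, col = "grey60")
  legend("bottomright", c("best", "current"), col = c("black", "grey60"),
         lwd = c(2, 1), bty = "n")
  invisible(x)
}
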