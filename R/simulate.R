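#' Specification of a synthetic mutation benchmark instance
#'
#' Describes the implanted-pathway benchmark: `n_pathways` disjoint gene sets
#' of size `set_size` are planted in a samples-by-genes binary matrix.  For
#' pathway i, each sample receives a driver mutation in one uniformly chosen
#' member with coverage probability `p_i = 1 - i * delta`; in samples where
#' that event fired, each remaining member is additionally mutated with leak
#' probability `p0` (so `p0` controls how exclusive the pathway is).  All
#' other ("passenger") genes mutate independently at a background rate; with
#' `background = "gene"` each passenger gene's rate is itself drawn once from
#' Uniform(0, `background_rate`), with `"fixed"` all passengers share
#' `background_rate`.
#'
#' @param n_genes total genes n (reference setting: 1000).
#' @param n_samples samples m (reference setting: 1000).
#' @param n_pathways implanted sets (reference setting: 5).
#' @param set_size genes per implanted set k (reference setting: 5).
#' @param delta per-set coverage decrement, `p_i = 1 - i * delta` (0.05).
#' @param p0 within-set co-mutation leak probability (0.04).
#' @param background `"gene"` or `"fixed"` passenger model.
#' @param background_rate maximum (or fixed) passenger mutation rate (0.02).
#' @param unconditional_leak apply the `p0` leak to every sample rather than
#'   only those whose coverage event fired.
#' @param shuffle_genes shuffle gene columns so implanted sets do not occupy
#'   a predictable block.
#' @param seed integer seed stored with the spec; used by
#'   [simulate_mutations()] unless overridden.
#' @return a list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_genes = 1000L, n_samples = 1000L,
                            n_pathways = 5L, set_size = 5L,
                            delta = 0.05, p0 = 0.04,
                            background = c("gene", "fixed"),
                            background_rate = 0.02,
                            unconditional_leak = FALSE,
                            shuffle_genes = TRUE,
                            seed = NULL) {
  spec <- list(
    n_genes = check_count(n_genes, "n_genes"),
    n_samples = check_count(n_samples, "n_samples"),
    n_pathways = check_count(n_pathways, "n_pathways"),
    set_size = check_count(set_size, "set_size"),
    delta = check_prob(delta, "delta", open_lo = TRUE, open_hi = TRUE),
    p0 = check_prob(p0, "p0"),
    background = match.arg(background),
    background_rate = check_prob(background_rate, "background_rate", open_hi = TRUE),
    unconditional_leak = isTRUE(unconditional_leak),
    shuffle_genes = isTRUE(shuffle_genes),
    seed = if (!is.null(seed)) as.integer(seed)
  )
  if (spec$n_pathways * spec$set_size > spec$n_genes) {
    stop_f("n_pathways * set_size = %d exceeds n_genes = %d",
           spec$n_pathways * spec$set_size, spec$n_genes)
  }
  p <- 1 - seq_len(spec$n_pathways) * spec$delta
  if (any(p <= 0)) {
    stop_f("coverage probabilities p_i = 1 - i * delta must stay positive; delta = %g is too large for %d pathways",
           spec$delta, spec$n_pathways)
  }
  spec$coverage_probs <- p
  structure(spec, class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf("Simulation spec: %d samples x %d genes; %d implanted sets of size %d\n",
              x$n_samples, x$n_genes, x$n_pathways, x$set_size))
  cat(sprintf("  coverage p_i = 1 - i * %g: %s; leak p0 = %g%s\n",
              x$delta, paste(format(x$coverage_probs), collapse = ", "), x$p0,
              if (x$unconditional_leak) " (unconditional)" else ""))
  cat(sprintf("  passenger background: %s rate %g\n", x$background, x$background_rate))
  invisible(x)
}

#' Simulate a mutation matrix with implanted driver pathways
#'
#' Realises the generative model described in [simulation_spec()].  Gene ids
#' are `g0001, g0002, ...` (ids follow their columns through the shuffle);
#' the implanted sets and their coverage probabilities are returned as ground
#' truth.
#'
#' @param spec a [simulation_spec()].
#' @param seed integer seed; defaults to `spec$seed`.  Identical seeds give
#'   bit-identical datasets.
#' @return a list of class `simulated_dataset` with elements `mutations`
#'   (binary matrix), `truth` (list of implanted gene-id vectors),
#'   `coverage_probs` and `spec`.
#' @examples
#' d <- simulate_mutations(simulation_spec(n_genes = 50, n_samples = 100,
#'                                         n_pathways = 2, set_size = 3,
#'                                         seed = 1))
#' pathway_weight(d$mutations, d$truth[[1]])
#' @export
simulate_mutations <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "simulation_spec"))
  m <- spec$n_samples
  n <- spec$n_genes
  k <- spec$set_size
  npath <- spec$n_pathways
  with_seed(seed, {
    A <- matrix(0L, m, n)
    for (i in seq_len(npath)) {
      members <- ((i - 1L) * k + 1L):(i * k)
      fired <- stats::runif(m) < spec$coverage_probs[i]
      chosen <- sample.int(k, m, replace = TRUE)
      block <- matrix(0L, m, k)
      block[cbind(which(fired), chosen[fired])] <- 1L
      leak <- matrix(stats::runif(m * k) < spec$p0, m, k)
      eligible <- if (spec$unconditional_leak) rep(TRUE, m) else fired
      block[eligible, ] <- block[eligible, , drop = FALSE] |
        leak[eligible, , drop = FALSE]
      A[, members] <- block
    }
    n_bg <- n - npath * k
    if (n_bg > 0L) {
      rates <- switch(spec$background,
        gene = stats::runif(n_bg, 0, spec$background_rate),
        fixed = rep(spec$background_rate, n_bg)
      )
      bg <- matrix(stats::runif(m * n_bg) < rep(rates, each = m), m, n_bg)
      A[, (npath * k + 1L):n] <- bg
    }
    storage.mode(A) <- "integer"
    perm <- if (spec$shuffle_genes) sample.int(n) else seq_len(n)
    A <- A[, perm, drop = FALSE]
    ids <- sprintf("g%0*d", nchar(n), seq_len(n))
    dimnames(A) <- list(sprintf("s%0*d", nchar(m), seq_len(m)), ids)
    # implanted column j sits at position match(j, perm) after the shuffle
    truth <- lapply(seq_len(npath), function(i) {
      members <- ((i - 1L) * k + 1L):(i * k)
      ids[match(members, perm)]
    })
    structure(list(mutations = A, truth = truth,
                   coverage_probs = spec$coverage_probs, spec = spec),
              class = "simulated_dataset")
  })
}

#' @export
print.simulated_dataset <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  truth sets: %s\n",
              paste(vapply(x$truth, paste, character(1), collapse = "+"),
                    collapse = "; ")))
  invisible(x)
}

#' Simulate expression profiles correlated within implanted pathways
#'
#' Single-factor Gaussian model per implanted pathway: members of pathway i
#' share a latent per-sample factor with loading `sqrt(within_corr)`, so the
#' expected Pearson correlation between any two members is `within_corr`;
#' passenger genes are independent noise.  This realises the phenomenon the
#' integrative score exploits — co-pathway genes are co-expressed, genes of
#' different pathways are not.
#'
#' @param dataset a `simulated_dataset` from [simulate_mutations()].
#' @param within_corr expected pairwise correlation within an implanted set,
#'   in \[0, 1).
#' @param noise_sd marginal standard deviation of every profile.
#' @param seed integer seed.
#' @return an expression matrix aligned with `dataset$mutations`.
#' @export
simulate_expression <- function(dataset, within_corr = 0.8, noise_sd = 1,
                                seed = NULL) {
  stopifnot(inherits(dataset, "simulated_dataset"))
  check_prob(within_corr, "within_corr", open_hi = TRUE)
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd <= 0) {
    stop_f("`noise_sd` must be a single positive number")
  }
  A <- dataset$mutations
  m <- nrow(A)
  with_seed(seed, {
    E <- matrix(stats::rnorm(m * ncol(A)), m, ncol(A), dimnames = dimnames(A))
    a <- sqrt(within_corr)
    for (set in dataset$truth) {
      f <- stats::rnorm(m)
      idx <- match(set, colnames(A))
      E[, idx] <- a * f + sqrt(1 - within_corr) * E[, idx, drop = FALSE]
    }
    E * noise_sd
  })
}
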