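#' Annealing schedule parameters for SAGA
#'
#' The temperature starts at `initial_temperature` (default `m/10`, chosen on
#' the scale of the weight, which is bounded by the sample count m) and is
#' multiplied by `cooling_factor` after every `steps_per_temperature`
#' proposals.  The run stops when the temperature drops below
#' `min_temperature` or after `max_stagnant_rounds` consecutive temperature
#' stages without an improvement of the best score.
#'
#' @param initial_temperature positive start temperature; `NULL` means `m/10`
#'   is filled in from the mutation matrix at fit time.
#' @param cooling_factor geometric cooling multiplier, strictly in (0, 1).
#' @param steps_per_temperature proposals evaluated at each temperature.
#' @param min_temperature positive floor ending the schedule.
#' @param max_stagnant_rounds stages without improvement before stopping.
#' @return a list of class `anneal_control`.
#' @export
anneal_control <- function(initial_temperature = NULL,
                           cooling_factor = 0.95,
                           steps_per_temperature = 50L,
                           min_temperature = 1e-3,
                           max_stagnant_rounds = 10L) {
  if (!is.null(initial_temperature)) {
    if (!is.numeric(initial_temperature) || length(initial_temperature) != 1L ||
        !is.finite(initial_temperature) || initial_temperature <= 0) {
      stop_f("`initial_temperature` must be a positive number (or NULL for m/10)")
    }
    if (min_temperature >= initial_temperature) {
      stop_f("`min_temperature` must be below `initial_temperature`")
    }
  }
  check_prob(cooling_factor, "cooling_factor", open_lo = TRUE, open_hi = TRUE)
  if (!is.numeric(min_temperature) || min_temperature <= 0) {
    stop_f("`min_temperature` must be positive")
  }
  structure(list(
    initial_temperature = initial_temperature,
    cooling_factor = as.numeric(cooling_factor),
    steps_per_temperature = check_count(steps_per_temperature, "steps_per_temperature"),
    min_temperature = as.numeric(min_temperature),
    max_stagnant_rounds = check_count(max_stagnant_rounds, "max_stagnant_rounds")
  ), class = "anneal_control")
}

#' Genetic-algorithm parameters
#'
#' Individuals are sorted tuples of k distinct gene indices.  Each generation
#' applies tournament selection (size 2), one-point crossover on the sorted
#' tuple with duplicate repair, and a mutation that swaps one member for a
#' random non-member; the best `elite_count` individuals survive unchanged.
#'
#' @param population_size individuals per generation.
#' @param generations generations for the standalone GA optimizer.
#' @param generations_per_proposal GA generations used to produce one SAGA
#'   proposal.
#' @param crossover_probability probability a child is produced by crossover.
#' @param mutation_probability per-individual probability of a member swap.
#' @param elite_count best individuals copied unchanged (must be <
#'   `population_size`).
#' @param greedy_seeds initial individuals built by greedy forward selection
#'   from the most frequently mutated genes (capped at `population_size - 1`);
#'   the rest of the initial population is uniform random.
#' @return a list of class `ga_control`.
#' @export
ga_control <- function(population_size = 100L,
                       generations = 100L,
                       generations_per_proposal = 1L,
                       crossover_probability = 0.9,
                       mutation_probability = 0.2,
                       elite_count = 1L,
                       greedy_seeds = 20L) {
  out <- structure(list(
    population_size = check_count(population_size, "population_size", min = 2L),
    generations = check_count(generations, "generations"),
    generations_per_proposal = check_count(generations_per_proposal,
                                           "generations_per_proposal"),
    crossover_probability = check_prob(crossover_probability, "crossover_probability"),
    mutation_probability = check_prob(mutation_probability, "mutation_probability"),
    elite_count = check_count(elite_count, "elite_count", min = 0L),
    greedy_seeds = check_count(greedy_seeds, "greedy_seeds", min = 0L)
  ), class = "ga_control")
  if (out$elite_count >= out$population_size) {
    stop_f("`elite_count` must be smaller than `population_size`")
  }
  out
}
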