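---
title: "Discovering mutated driver pathways from somatic mutation matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering mutated driver pathways from somatic mutation matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A cancer cohort is summarised as a binary mutation matrix $A$ with $m$
samples in rows and $n$ genes in columns; $A_{ig} = 1$ means gene $g$
carries a somatic mutation in sample $i$.  Two empirical regularities
motivate the score this package optimises.  First, a driver pathway is
mutated in most samples (*high coverage*): writing
$\Gamma(g) = \{i : A_{ig} = 1\}$ and
$\Gamma(M) = \bigcup_{g \in M} \Gamma(g)$ for a gene set $M$, the coverage
$|\Gamma(M)|$ should be large.  Second, one hit per pathway per tumour is
usually sufficient (*high exclusivity*), so the co-occurrence overlap
$\omega(M) = \sum_{g \in M} |\Gamma(g)| - |\Gamma(M)|$ should be small.
Both are combined into the weight

$$W(M) \;=\; |\Gamma(M)| - \omega(M) \;=\; 2\,|\Gamma(M)| - \sum_{g \in M} |\Gamma(g)|,$$

and the *maximum weight submatrix problem* asks for the $k$-gene set
maximising $W$.  The problem is NP-hard, and the landscape over $k$-sets is
deceptive in a specific way: any two frequently mutated genes co-occur by
chance in roughly $|\Gamma(g_1)||\Gamma(g_2)|/m$ samples, so a set mixing
genes from two different pathways pays a large overlap penalty, while each
complete pathway forms a deep, isolated basin.  Moving between basins
requires exchanging essentially every member, which is what defeats naive
local search.

When several gene sets tie (or nearly tie) on $W$, expression data can
discriminate: genes of one pathway tend to be co-expressed.  With an
expression matrix $E$ aligned to $A$, the integrative score is

$$F_{ME} \;=\; W(M) + \lambda\, R(E_M), \qquad
R(E_M) = \binom{k}{2}^{-1} \sum_{j_1 < j_2} |\mathrm{pcc}(x_{j_1}, x_{j_2})|,$$

the mean absolute pairwise Pearson correlation of the members' expression
profiles, $R \in [0, 1]$.  Typical settings are $\lambda = 1$ (pure
tie-breaking, since $W$ is integral and $\lambda R < 1$ distinguishes only
equal-$W$ sets) and $\lambda = 10$ (an outright preference for co-expressed
sets).  Both are exposed via the `lambda` argument; it must be given
explicitly when results are reported, as conclusions can differ between the
two settings.

## Search: SAGA and its baselines

`driver_pathways()` dispatches to four optimizers that share a solution
encoding (a sorted tuple of $k$ distinct column indices, which keeps the
$|M| = k$ constraint structural) and a fully deterministic seeding scheme.

**SAGA** (`saga_optimize()`) hybridises a generational genetic algorithm
with simulated annealing.  A persistent GA population (tournament selection
of size 2, one-point crossover on the sorted tuple with duplicate repair,
single-member mutation, one elite) generates each proposal in the
neighbourhood of the current solution; the proposal is refined to its greedy
1-swap local optimum and then subjected to the Metropolis rule: improvements
are always accepted, worse moves with probability $e^{\Delta S / T}$, with
$T$ following a geometric schedule ($T \leftarrow 0.95\,T$ every 50
proposals, starting from $T_0 = m/10$, on the natural scale of $W$).
A temperature stage that fails to improve the incumbent re-initialises the
population at random — the outer loop re-enters its GA-initialisation step —
so the run behaves as a record-keeping multi-start anneal.  The run stops at
$T < 10^{-3}$ or after 10 stagnant stages.

Two design elements deserve justification because a plainer hybrid fails.
First, *local-search refinement* (the memetic step): without it, offspring
rarely reach the bottom of any basin and the search returns mixed sets; the
greedy 1-swap descent is deterministic, cheap (bit-packed columns with
hardware popcounts in compiled code), and turns every proposal into a basin
optimum, so the Metropolis chain effectively compares basins rather than
arbitrary sets.  Second, *greedy seeding*: a few initial individuals are
grown by forward selection from the most frequently mutated genes
(`ga_control(greedy_seeds = 20)`).  Because within-pathway co-occurrence
(only via the leak process) is far below chance co-occurrence between
pathways, greedy growth from a pathway gene assembles that gene's own
pathway, planting whole-basin building blocks in the initial population.
Both elements change only how thoroughly the fixed objective is optimised,
never the objective or the data.

**GA baseline** (`ga_optimize()`): the same generational GA run standalone
for a fixed number of generations, with the refinement applied to each
generation's best offspring.  **MCMC baseline** (`mcmc_optimize()`): a
single-gene-swap Metropolis chain with stationary density $\propto c^{W(M)}$
($c = 2$ by default), reporting the best state visited; it has no
refinement or seeding, faithfully representing the sampling-based
predecessor approach.  **Exact oracle** (`exhaustive_optimize()`):
enumeration of all $\binom{n}{k}$ sets over bit-packed columns, feasible to
a few million candidates; ties are broken lexicographically on sorted gene
ids, making it fully deterministic.

With the integrative objective, the refinement step optimises the dominant
$W$ part and the full $F_{ME}$ decides acceptance and ranking; since
$\lambda R \le \lambda$ is small against between-basin weight differences,
this loses nothing in practice.  At $\lambda = 0$, $F_{ME} \equiv W$ and the
integrative fit takes the weight code path exactly, consuming the same
random numbers — seeded runs of the two objectives coincide by construction.

## Tunable parameters

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `k` | all fits | — | gene-set size searched (units: genes) |
| `lambda` | integrative fits | 1 | weight of $R(E_M)$; 1 = tie-breaking, 10 = correlation-seeking |
| `initial_temperature` | `anneal_control()` | $m/10$ | start $T$, on the scale of $W$ (bounded by $m$) |
| `cooling_factor` | `anneal_control()` | 0.95 | geometric decay per stage |
| `steps_per_temperature` | `anneal_control()` | 50 | proposals per stage |
| `min_temperature` | `anneal_control()` | $10^{-3}$ | schedule floor |
| `max_stagnant_rounds` | `anneal_control()` | 10 | stages without improvement before stopping |
| `population_size` | `ga_control()` | 100 | GA individuals |
| `crossover_probability` | `ga_control()` | 0.9 | per-child crossover rate |
| `mutation_probability` | `ga_control()` | 0.2 | per-child member-swap rate |
| `greedy_seeds` | `ga_control()` | 20 | forward-selected initial individuals |
| `iterations`, `c` | `mcmc_optimize()` | 20000, 2 | chain length and Metropolis base |
| `n_perm` | `permutation_test()` | 1000 | permutations (100 in the staged workflow) |

## The synthetic benchmark generator

`simulate_mutations()` realises the implanted-pathway benchmark that the
method family uses to measure optimizer accuracy.  Defaults:
$n = 1000$ genes, $m = 1000$ samples, five implanted sets of $k = 5$ genes.
For implanted set $M_i$ and each sample, a coverage event fires with
probability $p_i = 1 - i\,\Delta$ ($\Delta = 0.05$), mutating one uniformly
chosen member; in samples where it fired, each remaining member leaks to 1
independently with probability $p_0 = 0.04$.  The sentence defining the
leak admits two readings; the conditional one (leak only in covered rows)
is the default, the unconditional variant sits behind
`unconditional_leak = TRUE`.  Passenger genes mutate independently, each
with its own rate drawn once from $\mathrm{Uniform}(0, 0.02)$
(`background = "gene"`); a fixed-rate mode is also provided.  The original
background model was calibrated to an unpublished glioblastoma summary and
cannot be reproduced exactly; neither mode claims that fidelity.  The
sample count $m$ is likewise not recorded for the original benchmark;
$m = 1000$ is a realistic cohort scale at which the coverage signal
dominates sampling noise.  Implanted sets initially occupy the leading
columns and the column order is then shuffled (seeded) so no optimizer can
exploit layout.  `simulate_expression()` adds a single-factor Gaussian
model per pathway: members load $\sqrt{\rho}$ on a shared latent factor so
every within-pathway pair has expected correlation $\rho$
(`within_corr`, default 0.8), passengers are independent noise.

What the generator does *not* emulate: real mutation-frequency spectra
(long-tailed hypermutators, gene-length effects), copy-number segments that
mutate in blocks, subtype structure, or expression networks beyond one
factor per pathway.  Passing tests therefore demonstrate the machinery —
scoring, search, calibration of the null — not clinical validity on any
particular cohort.

## Significance and the staged workflow

The permutation null (`permute_mutations()`) reassigns each gene's
mutations to a uniformly random same-size subset of samples, preserving
per-gene frequencies exactly while destroying coverage/exclusivity
structure.  `permutation_test()` re-optimises each permuted matrix at the
same $k$ and reports the add-one estimator
$p = (1 + \#\{W_{\mathrm{null}} \ge W_{\mathrm{obs}}\})/(1 + n_{\mathrm{perm}})$,
which can never be zero and floors at $1/(n_{\mathrm{perm}}+1)$.
`iterative_discovery()` alternates fit, test and column removal so that
secondary pathways surface once the dominant one is taken out; genes
mutated in identical sample sets can first be merged with
`collapse_metagenes()` (ids joined with `+`, never merging mutation-free
genes, exposed as an explicit optional step since it matters for real
cohorts but is immaterial to the synthetic benchmark).

`accuracy_benchmark()` measures, per simulated replicate, whether each
stochastic optimizer attains the exact optimal weight.  The oracle
enumerates a candidate pool of all implanted genes plus the most frequently
mutated passengers (full enumeration over $\binom{1000}{5}$ being
impossible); a *match* means equal weight, not equal gene ids, because
distinct equal-weight optima are legitimate.  The MCMC baseline gets the
same number of objective evaluations SAGA spent on that replicate, so the
comparison is budget-fair.

## Numerical choices and degenerate inputs

* Ties everywhere resolve lexicographically (enumeration order for the
  oracle, first-found for strict improvements elsewhere), so every seeded
  run is bit-reproducible; seeds never leak into the caller's RNG stream.
* Correlations use pairwise-complete observations; a pair with fewer than 3
  complete values or zero variance is an error by default
  (`zero_variance = "error"`) and scores 0 under the permissive policy that
  the optimizers use internally, so a stray constant column cannot abort a
  long search.
* The empty gene set is rejected at the public boundary; optimizer
  bookkeeping never evaluates it.
* All-zero gene columns are valid, score $W = 0$ contributions, and are
  flagged but never merged by the metagene step.
* `k = n` leaves a single candidate set; all optimizers return it without
  sampling (the swap proposal does not exist in that case).

## Problem sizes used by the shipped checks

The test suite exercises exact enumeration against an independent
brute-force reimplementation on hundreds of small random matrices
($n \le 12$, $k \le 4$), optimizer-vs-oracle agreement on 100 instances at
$n = 15$, and the full benchmark geometry ($1000 \times 1000$, five
implanted pathways) at 15 replicates; `scripts/acceptance.R` runs the same
benchmark at 100 replicates.  These sizes were chosen so the whole suite
runs comfortably on a laptop while keeping binomial noise on the reported
accuracies within a few percentage points.

## Known limitations

* The weight treats all samples and genes symmetrically; there is no
  per-gene background mutation-rate model, so long or hypermutated genes
  can attract the optimizer on real cohorts (the permutation test guards
  the final call, not the search).
* Mutual exclusivity is assumed within a pathway only; co-occurring driver
  pathways are out of scope for the score.
* The oracle's candidate-pool restriction is exact only when the global
  optimum lies in the pool; for the benchmark's signal strengths this holds
  in practice, but pathological instances could defeat it.
* The integrative refinement optimises $W$ first; with $\lambda$ large
  enough that $\lambda R$ rivals between-basin weight gaps (roughly
  $\lambda \gtrsim 50$ at benchmark scale) the search may be suboptimal for
  the stated objective.
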